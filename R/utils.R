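# Internal helpers shared across modules.

# Raw byte codes for the DNA alphabet; alignments are manipulated as byte
# matrices (charToRaw) because per-column tabulation in R is fast on integers.
.BASE_CHARS <- c("A", "C", "G", "T")
.BASE_BYTES <- as.integer(charToRaw("ACGT"))
.GAP_BYTE <- as.integer(charToRaw("-"))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.5 always moves away from
#' zero) rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

# stop() with a message naming the offending field, used by all config
# constructors so validation errors are actionable.
.check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

.check_scalar_number <- function(x, field, min = -Inf, max = Inf,
                                 integer = FALSE) {
  .check_field(is.numeric(x) && length(x) == 1L && is.finite(x), field,
               "must be a single finite number")
  if (integer) .check_field(x == trunc(x), field, "must be an integer")
  .check_field(x >= min, field, sprintf("must be >= %s", format(min)))
  .check_field(x <= max, field, sprintf("must be <= %s", format(max)))
  invisible(x)
}

# Uniform random DNA string(s) of the given lengths (uses the current RNG
# stream; callers own seeding).
.random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(.BASE_CHARS, n, replace = TRUE), collapse = "")
  }, character(1))
}

# Convert equal-length sequence strings into an integer byte matrix,
# rows = sequences (named), columns = alignment columns.
.byte_matrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stop("sequences have unequal lengths; not an alignment", call. = FALSE)
  }
  m <- matrix(0L, nrow = length(seqs), ncol = n[1],
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    m[i, ] <- as.integer(charToRaw(seqs[[i]]))
  }
  m
}

.bytes_to_string <- function(bytes) rawToChar(as.raw(bytes))

# Reverse complement for plain character strings (ACGTN- safe).
.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(lapply(strsplit(x, "", fixed = TRUE), rev),
                                  paste, character(1), collapse = ""))
}

# Deterministic derived seed for a named pipeline stage, kept within the
# 32-bit integer range.
.stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}

# write.table with the fixed conventions used for all analytic TSV outputs
# (deterministic bytes: no quoting, no row names, "." decimal, LF endings).
.write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
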