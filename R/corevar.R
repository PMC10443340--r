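# Core-genome micro-diversity: per-family core alignments, occurrence-
# filtered SNP site extraction, SNPs/Mbp normalisation, pairwise SNP counts
# against a reference strain, and synonymous/non-synonymous classification
# of coding substitutions (translation table 11).

#' Core alignment container
#'
#' Equal-length aligned nucleotide sequences of one core family over all
#' genomes ('-' = gap). The reference row is always gap-free, so columns map
#' one-to-one onto reference gene coordinates and per-family alignments can
#' be concatenated.
#'
#' @param family family ID.
#' @param seqs named character vector of aligned sequences (names = genomes).
#' @param gene_ids named character vector of source gene IDs.
#' @return object of class `core_alignment`.
#' @export
core_alignment <- function(family, seqs, gene_ids = NULL) {
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  structure(list(family = family, genomes = names(seqs), seqs = seqs,
                 gene_ids = gene_ids),
            class = "core_alignment")
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("<core_alignment> %s: %d genomes x %d columns\n",
              x$family, length(x$seqs), nchar(x$seqs[[1]])))
  invisible(x)
}

#' Align the members of a core family
#'
#' If all members have equal length (the substitution-only case) the
#' sequences are already positionally aligned and returned as-is. Otherwise
#' each member is globally aligned to the reference member and projected
#' onto reference coordinates: columns where the reference would carry a gap
#' (insertions relative to the reference) are dropped, deletions appear as
#' '-' in the member row, and the reference row stays gap-free.
#'
#' @param members named character vector, exactly one sequence per genome.
#' @param reference genome ID of the reference strain.
#' @param family family ID for labelling.
#' @param config a [clustering_config()] supplying alignment scores.
#' @return a [core_alignment()].
#' @export
align_family <- function(members, reference, family = "family",
                         config = clustering_config()) {
  if (!reference %in% names(members)) {
    stop(sprintf("reference genome %s missing from family %s: not a core family",
                 reference, family), call. = FALSE)
  }
  if (anyDuplicated(names(members))) {
    stop("one member per genome required", call. = FALSE)
  }
  if (length(unique(nchar(members))) == 1L) {
    return(core_alignment(family, members))
  }
  ref_seq <- members[[reference]]
  sm <- Biostrings::nucleotideSubstitutionMatrix(config$match, config$mismatch)
  aligned <- vapply(names(members), function(g) {
    if (g == reference) return(ref_seq)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(members[[g]]), Biostrings::DNAString(ref_seq),
      type = "global", substitutionMatrix = sm,
      gapOpening = config$gap_opening, gapExtension = config$gap_extension)
    pa <- as.integer(charToRaw(as.character(Biostrings::pattern(aln))))
    sa <- as.integer(charToRaw(as.character(Biostrings::subject(aln))))
    keep <- sa != .GAP_BYTE
    .bytes_to_string(pa[keep])
  }, character(1))
  core_alignment(family, aligned)
}

#' Extract occurrence-filtered SNP sites from a core alignment
#'
#' A column is a SNP site when (after optionally dropping columns containing
#' any gap) at least two distinct bases occur and the summed occurrence of
#' all non-majority bases reaches `min_occurrence` of the genome collection.
#' Ambiguous bases (N) count as neither allele nor match.
#'
#' @param alignment a `core_alignment` (>= 2 rows).
#' @param config a [snp_calling_config()].
#' @return data.frame with one row per SNP site: `family`, `column0`
#'   (0-based column index within the family alignment), allele counts
#'   `A`,`C`,`G`,`T`, `n_alleles` and `minor_occurrence` (summed
#'   non-majority proportion of genomes).
#' @export
extract_snp_sites <- function(alignment, config = snp_calling_config()) {
  stopifnot(inherits(alignment, "core_alignment"))
  if (length(alignment$seqs) < 2L) {
    stop("need >= 2 aligned rows", call. = FALSE)
  }
  m <- .byte_matrix(alignment$seqs)
  n_genomes <- nrow(m)
  counts <- vapply(.BASE_BYTES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- .BASE_CHARS
  keep <- rep(TRUE, ncol(m))
  if (config$drop_gap_columns) {
    keep <- colSums(m == .GAP_BYTE) == 0L
  }
  n_alleles <- rowSums(counts > 0L)
  nonmajor <- rowSums(counts) - apply(counts, 1L, max)
  is_snp <- keep & n_alleles >= 2L &
    nonmajor >= config$min_occurrence * n_genomes - 1e-9
  idx <- which(is_snp)
  data.frame(family = rep(alignment$family, length(idx)),
             column0 = idx - 1L,
             A = as.integer(counts[idx, "A"]),
             C = as.integer(counts[idx, "C"]),
             G = as.integer(counts[idx, "G"]),
             T = as.integer(counts[idx, "T"]),
             n_alleles = as.integer(n_alleles[idx]),
             minor_occurrence = nonmajor[idx] / n_genomes,
             stringsAsFactors = FALSE)
}

#' Concatenate per-family core alignments
#'
#' @param alignments list of `core_alignment` objects over the same genomes.
#' @return a `core_alignment` labelled "concatenated" with a `offsets`
#'   attribute giving each family's 0-based start column.
#' @export
concat_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  genomes <- alignments[[1]]$genomes
  for (a in alignments) {
    if (!identical(sort(a$genomes), sort(genomes))) {
      stop("all alignments must cover the same genomes", call. = FALSE)
    }
  }
  seqs <- vapply(genomes, function(g) {
    paste(vapply(alignments, function(a) a$seqs[[g]], character(1)),
          collapse = "")
  }, character(1))
  widths <- vapply(alignments, function(a) nchar(a$seqs[[1]]), integer(1))
  out <- core_alignment("concatenated", seqs)
  attr(out, "offsets") <- setNames(cumsum(c(0L, widths[-length(widths)])),
                                   vapply(alignments, `[[`, character(1),
                                          "family"))
  out
}

#' SNP count normalised per megabase
#'
#' @param snp_count number of SNP sites.
#' @param normalization_length length in bp of the sequence the SNPs were
#'   counted on (the concatenated alignment, or a mean genome length --
#'   both conventions are meaningful; state which one you use).
#' @return SNPs per Mbp.
#' @export
snps_per_mbp <- function(snp_count, normalization_length) {
  if (!is.numeric(normalization_length) || normalization_length <= 0) {
    stop("normalization_length must be > 0", call. = FALSE)
  }
  snp_count * 1e6 / normalization_length
}

#' Pairwise SNP count between two aligned rows
#'
#' Number of columns where both characters are unambiguous bases and differ;
#' columns containing a gap or an ambiguous base are skipped.
#'
#' @param row,reference_row aligned sequences of equal length.
#' @return integer count.
#' @export
pairwise_snp_count <- function(row, reference_row) {
  if (nchar(row) != nchar(reference_row)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  x <- as.integer(charToRaw(row))
  y <- as.integer(charToRaw(reference_row))
  sum(x != y & x %in% .BASE_BYTES & y %in% .BASE_BYTES)
}

#' Classify codon substitutions as synonymous or non-synonymous
#'
#' Each differing position is assessed independently: the reference codon is
#' mutated at that position alone and translated with the bacterial genetic
#' code (translation table 11); the substitution is synonymous iff the amino
#' acid is unchanged (stop gain/loss counts as non-synonymous). Codons with
#' ambiguous bases are reported unclassifiable.
#'
#' @param reference_codon,variant_codon in-frame codons (3 bases).
#' @return data.frame with one row per differing position: `position`
#'   (1-3), `ref_base`, `var_base`, `ref_aa`, `var_aa`, `effect` in
#'   `synonymous` / `non_synonymous` / `unclassifiable`.
#' @export
classify_substitution <- function(reference_codon, variant_codon) {
  if (nchar(reference_codon) != 3L || nchar(variant_codon) != 3L) {
    stop("codons must be 3 bases", call. = FALSE)
  }
  code <- Biostrings::getGeneticCode("11")
  ref <- toupper(reference_codon); var <- toupper(variant_codon)
  rb <- strsplit(ref, "", fixed = TRUE)[[1]]
  vb <- strsplit(var, "", fixed = TRUE)[[1]]
  diffs <- which(rb != vb)
  out <- lapply(diffs, function(p) {
    mut <- rb; mut[p] <- vb[p]
    mutc <- paste(mut, collapse = "")
    if (!all(c(rb, vb[p]) %in% .BASE_CHARS)) {
      return(data.frame(position = p, ref_base = rb[p], var_base = vb[p],
                        ref_aa = NA_character_, var_aa = NA_character_,
                        effect = "unclassifiable", stringsAsFactors = FALSE))
    }
    aa_ref <- unname(code[ref]); aa_var <- unname(code[mutc])
    data.frame(position = p, ref_base = rb[p], var_base = vb[p],
               ref_aa = aa_ref, var_aa = aa_var,
               effect = if (aa_ref == aa_var) "synonymous" else
                 "non_synonymous",
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(position = integer(0), ref_base = character(0),
                      var_base = character(0), ref_aa = character(0),
                      var_aa = character(0), effect = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Genome-wide core SNP summary against a reference strain
#'
#' For each non-reference genome: the total number of differing sites
#' against the reference over the concatenated core families (cgSNPs) and,
#' for sites within complete in-frame codons, the synonymous /
#' non-synonymous tally (each differing site assessed by mutating the
#' reference codon at that site alone). Percentages are rounded half away
#' from zero.
#'
#' @param alignments list of `core_alignment` objects (reference present in
#'   each; reference rows gap-free).
#' @param reference reference genome ID.
#' @return list with `per_genome` (data.frame genome, snps, syn, nonsyn,
#'   pct_nonsyn) and `total` (summed tallies with overall pct_nonsyn).
#' @export
genomewide_snp_summary <- function(alignments, reference) {
  stopifnot(length(alignments) >= 1L)
  genomes <- setdiff(alignments[[1]]$genomes, reference)
  code <- Biostrings::getGeneticCode("11")
  tot <- matrix(0L, nrow = length(genomes), ncol = 3L,
                dimnames = list(genomes, c("snps", "syn", "nonsyn")))
  for (a in alignments) {
    if (!reference %in% a$genomes) {
      stop(sprintf("reference %s missing from family %s", reference,
                   a$family), call. = FALSE)
    }
    refb <- as.integer(charToRaw(a$seqs[[reference]]))
    L <- length(refb)
    n_codons <- L %/% 3L
    ref_chars <- strsplit(a$seqs[[reference]], "", fixed = TRUE)[[1]]
    for (g in genomes) {
      gb <- as.integer(charToRaw(a$seqs[[g]]))
      diff <- which(refb != gb & refb %in% .BASE_BYTES &
                      gb %in% .BASE_BYTES)
      tot[g, "snps"] <- tot[g, "snps"] + length(diff)
      for (p in diff) {
        ci <- (p - 1L) %/% 3L
        if (ci >= n_codons) next  # trailing incomplete codon
        cstart <- ci * 3L + 1L
        refc <- ref_chars[cstart:(cstart + 2L)]
        if (!all(refc %in% .BASE_CHARS)) next
        mut <- refc
        mut[p - cstart + 1L] <- rawToChar(as.raw(gb[p]))
        same <- code[[paste(refc, collapse = "")]] ==
          code[[paste(mut, collapse = "")]]
        if (same) tot[g, "syn"] <- tot[g, "syn"] + 1L
        else tot[g, "nonsyn"] <- tot[g, "nonsyn"] + 1L
      }
    }
  }
  per_genome <- data.frame(
    genome = genomes,
    snps = tot[, "snps"], syn = tot[, "syn"], nonsyn = tot[, "nonsyn"],
    pct_nonsyn = ifelse(tot[, "syn"] + tot[, "nonsyn"] > 0,
                        round_half_away(100 * tot[, "nonsyn"] /
                                          (tot[, "syn"] + tot[, "nonsyn"])),
                        NA_real_),
    stringsAsFactors = FALSE)
  rownames(per_genome) <- NULL
  total <- list(snps = sum(tot[, "snps"]), syn = sum(tot[, "syn"]),
                nonsyn = sum(tot[, "nonsyn"]))
  total$pct_nonsyn <- if (total$syn + total$nonsyn > 0) {
    round_half_away(100 * total$nonsyn / (total$syn + total$nonsyn))
  } else NA_real_
  list(per_genome = per_genome, total = total)
}

#' Minimal variant table keyed to reference gene coordinates
#'
#' Reformats extracted SNP sites as a VCF-like table anchored on the
#' reference strain: because reference rows are gap-free, alignment columns
#' map one-to-one onto reference gene positions (1-based).
#'
#' @param alignments named list of `core_alignment` objects.
#' @param snp_sites data.frame from [extract_snp_sites()] over those
#'   alignments.
#' @param reference reference genome ID.
#' @return data.frame: `family`, `ref_gene`, `pos` (1-based within the
#'   reference gene), `ref` (reference allele), `alt` (comma-separated
#'   non-reference alleles), allele counts.
#' @export
reference_variant_table <- function(alignments, snp_sites, reference) {
  if (nrow(snp_sites) == 0L) {
    return(data.frame(family = character(0), ref_gene = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  out <- snp_sites
  out$pos <- out$column0 + 1L
  out$ref <- NA_character_
  out$alt <- NA_character_
  out$ref_gene <- NA_character_
  for (fam in unique(out$family)) {
    a <- alignments[[fam]]
    if (is.null(a) || !reference %in% a$genomes) {
      stop(sprintf("alignment for family %s with reference %s required",
                   fam, reference), call. = FALSE)
    }
    rows <- which(out$family == fam)
    refseq <- a$seqs[[reference]]
    out$ref[rows] <- substring(refseq, out$pos[rows], out$pos[rows])
    gid <- if (!is.null(a$gene_ids)) a$gene_ids[[reference]] else reference
    out$ref_gene[rows] <- gid
    for (r in rows) {
      present <- .BASE_CHARS[unlist(out[r, .BASE_CHARS]) > 0]
      out$alt[r] <- paste(setdiff(present, out$ref[r]), collapse = ",")
    }
  }
  out[, c("family", "ref_gene", "pos", "ref", "alt",
          .BASE_CHARS, "n_alleles", "minor_occurrence")]
}

#' Build core alignments for a set of families
#'
#' Convenience wrapper: extracts each core family's member genes from the
#' genomes and aligns them with [align_family()].
#'
#' @param table a `gene_family_table`.
#' @param genomes named list of `genome_record` objects.
#' @param families family IDs to align (default: the core families).
#' @param reference reference genome ID.
#' @param config a [clustering_config()].
#' @return named list of `core_alignment` objects.
#' @export
build_core_alignments <- function(table, genomes, families = NULL,
                                  reference, config = clustering_config()) {
  if (is.null(families)) families <- classify_families(table)$core
  seq_cache <- lapply(genomes, gene_sequences)
  names(seq_cache) <- vapply(genomes, `[[`, character(1), "strain")
  m <- table$members
  out <- lapply(families, function(fam) {
    rows <- m[m$family == fam, , drop = FALSE]
    # paralogs: keep the lexicographically first gene per genome
    rows <- rows[!duplicated(rows$genome), , drop = FALSE]
    members <- setNames(
      vapply(seq_len(nrow(rows)), function(i)
        seq_cache[[rows$genome[i]]][[rows$gene_id[i]]], character(1)),
      rows$genome)
    a <- align_family(members, reference, family = fam, config = config)
    a$gene_ids <- setNames(rows$gene_id, rows$genome)
    a
  })
  setNames(out, families)
}
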