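# Brute-force oracles and toy-object builders shared across the test files.
# Every oracle here is deliberately naive (per-column loops, fixed substring
# scans, exhaustive enumeration) and independent of the package internals.

# per-column SNP scan: returns 0-based columns that are SNP sites under the
# occurrence filter, recounted with plain loops
bf_snp_sites <- function(seqs, min_occurrence = 0.2, drop_gap_columns = TRUE) {
  rows <- strsplit(seqs, "", fixed = TRUE)
  L <- length(rows[[1]])
  n <- length(rows)
  out <- integer(0)
  for (j in seq_len(L)) {
    col <- vapply(rows, `[[`, character(1), j)
    if (drop_gap_columns && any(col == "-")) next
    bases <- col[col %in% c("A", "C", "G", "T")]
    tab <- table(bases)
    if (length(tab) < 2) next
    nonmajor <- sum(tab) - max(tab)
    if (nonmajor >= min_occurrence * n - 1e-9) out <- c(out, j - 1L)
  }
  out
}

# exact full-read substring search on both strands
bf_read_matches <- function(read, marker) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  grepl(read, marker, fixed = TRUE) || grepl(rc, marker, fixed = TRUE)
}

# Jukes-Cantor expected proportion of differing sites at divergence d
# (expected substitutions per site along the path between two tips)
jc_expected_p <- function(d) 0.75 * (1 - exp(-4 / 3 * d))

# independent translate-and-compare classification of a single-base codon
# change (seqinr's translation engine, bacterial code)
oracle_classify <- function(ref_codon, var_codon) {
  aa1 <- seqinr::translate(seqinr::s2c(ref_codon), numcode = 11)
  aa2 <- seqinr::translate(seqinr::s2c(var_codon), numcode = 11)
  if (aa1 == aa2) "synonymous" else "non_synonymous"
}

# naive single-linkage components from a logical adjacency matrix
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# random ungapped alignment with planted column variability
random_alignment <- function(n_rows, n_cols, p_variant = 0.1) {
  base <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  rows <- replicate(n_rows, {
    r <- base
    flip <- runif(n_cols) < p_variant
    r[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
    paste(r, collapse = "")
  })
  setNames(rows, sprintf("g%02d", seq_len(n_rows)))
}

# build a genome_record from explicit gene sequences laid on one contig
toy_genome <- function(strain, gene_seqs, spacer = 600L, products = NULL) {
  set.seed(sum(utf8ToInt(strain)))
  fams <- names(gene_seqs)
  if (is.null(products)) products <- rep("hypothetical protein", length(fams))
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  pieces <- character(0)
  starts <- integer(length(fams))
  pos <- 0L
  for (i in seq_along(fams)) {
    sp <- rand(spacer)
    pieces <- c(pieces, sp, gene_seqs[[i]])
    pos <- pos + spacer
    starts[i] <- pos + 1L
    pos <- pos + nchar(gene_seqs[[i]])
  }
  pieces <- c(pieces, rand(spacer))
  contig <- paste(pieces, collapse = "")
  contig_name <- paste0(strain, "_c1")
  genes <- data.frame(
    gene_id = paste(strain, fams, sep = "_"), family = fams,
    contig = contig_name, start = starts,
    end = starts + nchar(gene_seqs) - 1L, strand = "+",
    length = nchar(gene_seqs), product = products,
    stringsAsFactors = FALSE)
  structure(list(strain = strain,
                 contigs = setNames(contig, contig_name), genes = genes),
            class = "genome_record")
}

# family table straight from a list of genome_records whose gene families
# are already known (the `family` column)
toy_family_table <- function(genomes) {
  members <- do.call(rbind, lapply(genomes, function(g)
    data.frame(family = g$genes$family, genome = g$strain,
               gene_id = g$genes$gene_id, stringsAsFactors = FALSE)))
  gene_family_table(members, sort(vapply(genomes, `[[`, character(1),
                                         "strain")))
}

# family partition key: sorted "member,member,..." strings, one per family
partition_key <- function(members_df) {
  f <- split(members_df$gene_id, members_df$family)
  sort(unname(vapply(f, function(x) paste(sort(x), collapse = ","),
                     character(1))))
}

# does an unrooted tree contain the bipartition separating `tips`?
tree_has_split <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  lab <- attr(pp, "labels")
  all_tips <- sort(lab)
  target <- sort(tips)
  other <- sort(setdiff(all_tips, target))
  for (p in pp) {
    side <- sort(lab[p])
    if (identical(side, target) || identical(side, other)) return(TRUE)
  }
  FALSE
}
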