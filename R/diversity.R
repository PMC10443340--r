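# Per-gene variability statistics, highly-variable-gene (HVG) detection by
# the Q3 + 1.5*IQR outlier rule, p-distance matrices, neighbour-joining
# phylogenomics with bootstrap support, and reference strain selection.

#' Per-gene SNP statistics against a reference strain
#'
#' For every core family, the pairwise SNP count of each non-reference row
#' against the reference row; the family's variability is the mean (and SD)
#' over the non-reference genomes. Setting `all_pairs = TRUE` averages over
#' all genome pairs instead.
#'
#' @param alignments named list of `core_alignment` objects.
#' @param reference reference genome ID.
#' @param all_pairs average over all pairs instead of all-vs-reference.
#' @return data.frame: `family`, `mean_snps`, `sd_snps`, `n_comparisons`.
#' @export
per_gene_snp_stats <- function(alignments, reference, all_pairs = FALSE) {
  out <- lapply(alignments, function(a) {
    m <- .byte_matrix(a$seqs)
    ok <- colSums(matrix(m %in% .BASE_BYTES, nrow = nrow(m))) == nrow(m)
    if (all_pairs) {
      n <- nrow(m)
      cnt <- numeric(0)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        cnt <- c(cnt, sum(m[i, ] != m[j, ] & ok))
      }
    } else {
      if (!reference %in% a$genomes) {
        stop(sprintf("reference %s missing from family %s", reference,
                     a$family), call. = FALSE)
      }
      refv <- m[reference, ]
      others <- setdiff(rownames(m), reference)
      cnt <- vapply(others, function(g) sum(m[g, ] != refv & ok), numeric(1))
    }
    data.frame(family = a$family, mean_snps = mean(cnt),
               sd_snps = if (length(cnt) > 1L) sd(cnt) else NA_real_,
               n_comparisons = length(cnt), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect highly variable genes by the IQR outlier rule
#'
#' Quartiles of the per-family mean SNP counts are computed by linear
#' interpolation of the order statistics (R quantile type 7); a family is an
#' HVG iff its mean strictly exceeds Q3 + 1.5*IQR.
#'
#' @param stats data.frame from [per_gene_snp_stats()] (>= 4 families).
#' @return list with `hvgs` (family IDs, ordered by decreasing mean),
#'   `cutoff`, `q1`, `q3`.
#' @export
detect_hvgs <- function(stats) {
  if (nrow(stats) < 4L) stop("need >= 4 families", call. = FALSE)
  qs <- quantile(stats$mean_snps, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- qs[2] + 1.5 * (qs[2] - qs[1])
  sel <- stats$family[stats$mean_snps > cutoff]
  sel <- sel[order(-stats$mean_snps[match(sel, stats$family)], sel)]
  list(hvgs = sel, cutoff = cutoff, q1 = qs[1], q3 = qs[2])
}

#' Most conserved genes (below the 25th percentile)
#'
#' @param stats data.frame from [per_gene_snp_stats()] (>= 4 families).
#' @return family IDs whose mean SNP count is strictly below Q1.
#' @export
conserved_genes <- function(stats) {
  if (nrow(stats) < 4L) stop("need >= 4 families", call. = FALSE)
  q1 <- quantile(stats$mean_snps, 0.25, type = 7, names = FALSE)
  sort(stats$family[stats$mean_snps < q1])
}

#' Classify families as conserved / typical / HVG
#'
#' @param stats data.frame from [per_gene_snp_stats()].
#' @return `stats` with an added `class` column.
#' @export
classify_variability <- function(stats) {
  hv <- detect_hvgs(stats)
  cons <- conserved_genes(stats)
  stats$class <- "typical"
  stats$class[stats$family %in% cons] <- "conserved"
  stats$class[stats$family %in% hv$hvgs] <- "HVG"
  stats
}

#' p-distance matrix of an alignment
#'
#' Pairwise proportion of differing columns among columns where both rows
#' carry unambiguous bases.
#'
#' @param alignment a `core_alignment` (>= 3 rows).
#' @return symmetric numeric matrix with genome dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "core_alignment"))
  m <- .byte_matrix(alignment$seqs)
  if (nrow(m) < 3L) stop("need >= 3 rows", call. = FALSE)
  .p_dist_bytes(m)
}

#' Neighbour-joining tree
#'
#' Classical neighbour joining (Saitou-Nei Q-criterion with the standard
#' branch-length updates). Ties in the Q-matrix are broken deterministically
#' by the lexicographic order of the joined groups' smallest taxon labels.
#' Negative branch lengths are clamped to zero with the deficit shifted to
#' the sister branch.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n0 <- nrow(D)
  if (n0 < 3L) stop("need >= 3 taxa", call. = FALSE)
  labels <- rownames(D)
  # each active node carries a newick fragment and its smallest taxon label
  frags <- labels
  minlab <- labels
  act <- D
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (nrow(act) > 3L) {
    n <- nrow(act)
    r <- rowSums(act)
    Q <- (n - 2) * act - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(minlab[ij[1]], minlab[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    dij <- act[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- dij - bi
    b <- clamp_pair(bi, bj)
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frags[i], b[1], frags[j], b[2])
    new_min <- min(minlab[i], minlab[j])
    dnew <- (act[i, ] + act[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    frags <- c(frags[keep], new_frag)
    minlab <- c(minlab[keep], new_min)
    rownames(act) <- colnames(act) <- NULL
  }
  # final star join of the last three nodes (three-point formulas)
  d12 <- act[1, 2]; d13 <- act[1, 3]; d23 <- act[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  b <- pmax(c(b1, b2, b3), 0)
  ord <- order(minlab)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frags[ord[1]], b[ord[1]], frags[ord[2]], b[ord[2]],
                 frags[ord[3]], b[ord[3]])
  ape::read.tree(text = nwk)
}

# canonical bipartition keys of a tree's internal edges: each key is the
# sorted tip set on the side not containing the alphabetically first taxon
.split_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  lab <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- lab[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0L || length(side) >= ntip - 1L) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, character(1))
  keys
}

#' Bootstrap support for the neighbour-joining core tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for every internal split of the full-alignment
#' tree the percentage of replicates containing it. Splits below 50 are
#' reported too; filtering is left to display.
#'
#' @param alignment a concatenated `core_alignment` (>= 4 taxa).
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return the NJ `phylo` tree with support percentages as `node.label`
#'   (empty for the root node) and a `support` data.frame attribute.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  stopifnot(inherits(alignment, "core_alignment"))
  m <- .byte_matrix(alignment$seqs)
  if (nrow(m) < 4L) stop("need >= 4 taxa", call. = FALSE)
  oh <- .onehot_bases(m)
  ref_tree <- neighbor_joining(.p_dist_onehot(oh))
  ref_keys <- .split_keys(ref_tree)
  tally <- setNames(numeric(length(ref_keys)), ref_keys)
  set.seed(as.integer(seed))
  L <- ncol(m)
  for (b in seq_len(n_replicates)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    Db <- .p_dist_onehot(oh, w)
    keys_b <- .split_keys(neighbor_joining(Db))
    hit <- ref_keys %in% keys_b[!is.na(keys_b)]
    tally[hit] <- tally[hit] + 1
  }
  support <- 100 * tally / n_replicates
  ref_tree$node.label <- ifelse(is.na(ref_keys), "",
                                format(support, trim = TRUE, digits = 4))
  sup_df <- data.frame(split = ref_keys, support = unname(support),
                       stringsAsFactors = FALSE)
  attr(ref_tree, "support") <- sup_df[!is.na(sup_df$split), , drop = FALSE]
  ref_tree
}

# p-distance from a byte matrix with per-column weights (internal; used by
# bootstrap, where the weights are resampling multiplicities). Weighted
# match and comparable-column counts are crossproducts of one-hot base
# indicators, so each bootstrap replicate costs a few small BLAS calls
# instead of a pass over every taxon pair.
.onehot_bases <- function(m) {
  n <- nrow(m)
  oh <- lapply(.BASE_BYTES, function(b) matrix(as.numeric(m == b), nrow = n))
  oh$valid <- matrix(as.numeric(m %in% .BASE_BYTES), nrow = n)
  oh$labels <- rownames(m)
  oh
}

.p_dist_onehot <- function(oh, w = NULL) {
  valid <- oh$valid
  n <- nrow(valid)
  if (is.null(w)) {
    vw <- valid
    comp <- vw %*% t(valid)
    matches <- matrix(0, n, n)
    for (k in 1:4) matches <- matches + oh[[k]] %*% t(oh[[k]])
  } else {
    vw <- valid * rep(w, each = n)
    comp <- vw %*% t(valid)
    matches <- matrix(0, n, n)
    for (k in 1:4) {
      matches <- matches + (oh[[k]] * rep(w, each = n)) %*% t(oh[[k]])
    }
  }
  if (any(comp[upper.tri(comp)] == 0)) {
    stop("a taxon pair has no comparable columns", call. = FALSE)
  }
  D <- 1 - matches / comp
  diag(D) <- 0
  dimnames(D) <- list(oh$labels, oh$labels)
  D
}

.p_dist_bytes <- function(m, w = NULL) {
  .p_dist_onehot(.onehot_bases(m), w)
}

#' Select the most divergent strain as reference
#'
#' The genome maximising the mean distance to all other genomes (the
#' deepest split); ties broken by lexicographic genome ID.
#'
#' @param D symmetric distance matrix with genome dimnames (>= 2 taxa).
#' @return genome ID.
#' @export
select_reference_strain <- function(D) {
  if (nrow(D) < 2L) stop("need >= 2 taxa", call. = FALSE)
  mean_d <- rowSums(D) / (nrow(D) - 1L)
  ids <- rownames(D)
  ids[order(-mean_d, ids)][1L]
}

#' Neighbour-joining tree restricted to the HVG families
#'
#' Concatenates the alignments of the given HVG families only, then applies
#' [p_distance_matrix()] and [neighbor_joining()].
#'
#' @param alignments named list of `core_alignment` objects.
#' @param hvg_families HVG family IDs (non-empty).
#' @return unrooted `phylo` tree.
#' @export
hvg_tree <- function(alignments, hvg_families) {
  if (length(hvg_families) == 0L) stop("empty HVG set", call. = FALSE)
  missing <- setdiff(hvg_families, names(alignments))
  if (length(missing) > 0L) {
    stop(sprintf("alignments missing for HVG families: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  concat <- concat_alignments(alignments[hvg_families])
  neighbor_joining(p_distance_matrix(concat))
}
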