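# Pangenome construction: all-vs-all gene comparison with a shared-k-mer
# prefilter, orthologous families as connected components of the
# identity/coverage threshold graph, core/accessory/unique partition,
# accumulation curves, gene-family ANI and dereplication.

# ---- pairwise identity -------------------------------------------------

#' Global identity and coverage between two genes
#'
#' Ends-free global (overlap) dynamic-programming alignment. Identity is
#' matches / aligned columns (end overhangs excluded; `N` never counts as a
#' match); coverage is the aligned span as a fraction of the longer
#' sequence.
#'
#' @param a,b nucleotide sequences (character strings, A/C/G/T/N).
#' @param config a [clustering_config()] supplying alignment scores.
#' @return named numeric vector `c(identity=, coverage=)`.
#' @export
pairwise_gene_identity <- function(a, b, config = clustering_config()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (a == b) return(c(identity = 1, coverage = 1))
  sm <- Biostrings::nucleotideSubstitutionMatrix(config$match, config$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sm, gapOpening = config$gap_opening,
    gapExtension = config$gap_extension)
  pa <- as.integer(charToRaw(as.character(Biostrings::pattern(aln))))
  sa <- as.integer(charToRaw(as.character(Biostrings::subject(aln))))
  ncols <- length(pa)
  if (ncols == 0L) return(c(identity = 0, coverage = 0))
  matches <- sum(pa == sa & pa %in% .BASE_BYTES)
  c(identity = matches / ncols,
    coverage = min(1, ncols / max(nchar(a), nchar(b))))
}

# Ungapped positional identity for equal-length sequences (exact for the
# substitution-only regime; used as the clustering/ANI fast path).
.ungapped_identity <- function(a, b) {
  x <- as.integer(charToRaw(a)); y <- as.integer(charToRaw(b))
  sum(x == y & x %in% .BASE_BYTES) / length(x)
}

# identity/coverage with optional fast path (equal lengths, ungapped
# identity already above threshold -> skip the DP).
.gene_identity <- function(a, b, config) {
  if (config$fast_path && nchar(a) == nchar(b)) {
    id0 <- .ungapped_identity(a, b)
    if (id0 >= config$min_identity) {
      return(c(identity = id0, coverage = 1))
    }
  }
  pairwise_gene_identity(a, b, config)
}

# ---- k-mer prefilter ---------------------------------------------------

# Candidate gene pairs sharing at least one k-mer (enumerated at
# `stride`). Returns a 2-column integer matrix of index pairs (i < j),
# lexicographically sorted; indices refer to `seqs` order.
.kmer_candidate_pairs <- function(seqs, k, stride) {
  kmer <- NULL; gene <- NULL; i <- NULL; j <- NULL  # NSE notes
  tabs <- lapply(seq_along(seqs), function(idx) {
    s <- seqs[[idx]]
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq.int(1L, L - k + 1L, by = stride)
    data.table::data.table(kmer = unique(substring(s, starts,
                                                   starts + k - 1L)),
                           gene = idx)
  })
  dt <- data.table::rbindlist(tabs)
  if (nrow(dt) == 0L) return(matrix(integer(0), ncol = 2))
  data.table::setkey(dt, kmer)
  pairs <- dt[dt, on = "kmer", allow.cartesian = TRUE
              ][gene < i.gene, .(i = gene, j = i.gene)]
  pairs <- unique(pairs)
  data.table::setorder(pairs, i, j)
  as.matrix(pairs)
}

# iterative union-find root lookup (no mutation; chains stay short because
# unions always hang the larger root under the smaller one at our scales)
.uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

# ---- family table ------------------------------------------------------

#' Gene family (COG) table
#'
#' Container for gene-to-family assignments across a genome collection.
#'
#' @param members data.frame with columns `family`, `genome`, `gene_id`.
#' @param genomes character vector of all genome labels (including any with
#'   no assigned gene).
#' @return object of class `gene_family_table` with elements `members`,
#'   `genomes` and `counts` (family x genome paralog-count matrix).
#' @export
gene_family_table <- function(members, genomes) {
  stopifnot(all(c("family", "genome", "gene_id") %in% names(members)))
  fams <- sort(unique(members$family))
  counts <- matrix(0L, nrow = length(fams), ncol = length(genomes),
                   dimnames = list(fams, genomes))
  tb <- table(members$family, members$genome)
  counts[rownames(tb), colnames(tb)] <- tb
  structure(list(members = members[order(members$family, members$genome,
                                         members$gene_id), , drop = FALSE],
                 genomes = genomes, counts = counts),
            class = "gene_family_table")
}

#' Presence/absence matrix of a family table
#' @param table a `gene_family_table`.
#' @return logical matrix, families x genomes.
#' @export
presence_matrix <- function(table) {
  stopifnot(inherits(table, "gene_family_table"))
  table$counts > 0L
}

#' @export
print.gene_family_table <- function(x, ...) {
  cat(sprintf("<gene_family_table> %d families x %d genomes (%d genes)\n",
              nrow(x$counts), length(x$genomes), nrow(x$members)))
  invisible(x)
}

#' Cluster genes of a genome collection into orthologous families
#'
#' Builds a graph over all genes with an edge wherever the alignment
#' identity and coverage reach the configured thresholds (candidate pairs
#' restricted to those sharing a k-mer); families are the connected
#' components, deterministically identified by their lexicographically
#' smallest member gene ID. The result is independent of genome and gene
#' input order.
#'
#' @param genomes named list of `genome_record` objects.
#' @param config a [clustering_config()].
#' @return a [gene_family_table()].
#' @export
cluster_gene_families <- function(genomes, config = clustering_config()) {
  stopifnot(length(genomes) >= 1L)
  gene_tab <- do.call(rbind, lapply(genomes, function(g) {
    data.frame(genome = g$strain, gene_id = g$genes$gene_id,
               seq = unname(gene_sequences(g)), stringsAsFactors = FALSE)
  }))
  if (nrow(gene_tab) == 0L) stop("no genes to cluster", call. = FALSE)
  gene_tab <- gene_tab[order(gene_tab$gene_id), , drop = FALSE]
  n <- nrow(gene_tab)
  cand <- .kmer_candidate_pairs(gene_tab$seq, config$prefilter_k,
                                config$prefilter_stride)
  parent <- seq_len(n)
  bytes <- lapply(gene_tab$seq, function(s) as.integer(charToRaw(s)))
  if (nrow(cand) > 0L) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri == rj) next  # edge cannot change the components
      idcov <- .gene_identity(gene_tab$seq[i], gene_tab$seq[j], config)
      if (idcov[["identity"]] >= config$min_identity &&
          idcov[["coverage"]] >= config$min_coverage) {
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  # Exact-k-mer seeding cannot see highly divergent ortholog pairs (at 70%
  # identity a shared 15-mer is not guaranteed), so every equal-length pair
  # is additionally screened by ungapped positional identity -- the optimal
  # alignment in the substitution-only regime. This keeps the candidate
  # generation lossless for point-mutation divergence of any depth.
  lens <- nchar(gene_tab$seq)
  for (grp in split(seq_len(n), lens)) {
    if (length(grp) < 2L) next
    for (a in seq_len(length(grp) - 1L)) for (b in (a + 1L):length(grp)) {
      i <- grp[a]; j <- grp[b]
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri == rj) next
      x <- bytes[[i]]; y <- bytes[[j]]
      id0 <- sum(x == y & x %in% .BASE_BYTES) / length(x)
      if (id0 >= config$min_identity) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(x) .uf_find(parent, x), integer(1))
  fam_id <- ave(gene_tab$gene_id, roots, FUN = min)
  members <- data.frame(family = fam_id, genome = gene_tab$genome,
                        gene_id = gene_tab$gene_id, stringsAsFactors = FALSE)
  gene_family_table(members, sort(vapply(genomes, `[[`, character(1),
                                         "strain")))
}

# ---- partition and curves ----------------------------------------------

#' Partition families into core, accessory and unique
#'
#' Core families are present in every genome, unique families in exactly
#' one; the remainder is accessory. Per-genome unique-gene counts are the
#' numbers of genes belonging to that genome's unique families.
#'
#' @param table a `gene_family_table`.
#' @return list with `core`, `accessory`, `unique` (family ID vectors),
#'   `unique_counts` (named integer per genome) and `summary` (data.frame).
#' @export
classify_families <- function(table) {
  stopifnot(inherits(table, "gene_family_table"))
  pres <- presence_matrix(table)
  n_genomes <- ncol(pres)
  n_pres <- rowSums(pres)
  core <- rownames(pres)[n_pres == n_genomes]
  unique_f <- rownames(pres)[n_pres == 1L]
  accessory <- setdiff(rownames(pres), c(core, unique_f))
  uc <- colSums(table$counts[unique_f, , drop = FALSE])
  list(core = core, accessory = accessory, unique = unique_f,
       unique_counts = uc,
       summary = data.frame(
         class = c("core", "accessory", "unique"),
         n_families = c(length(core), length(accessory), length(unique_f)),
         stringsAsFactors = FALSE))
}

#' Pangenome and core-genome accumulation curves
#'
#' For each of `n_permutations` random genome orderings, the cumulative
#' pangenome (union of families) and core genome (intersection) sizes as
#' genomes are added, with a median/quartile summary across permutations.
#'
#' @param table a `gene_family_table`.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed integer seed.
#' @return list with `curves` (permutation-level data.frame) and `summary`
#'   (per number of genomes: median and quartiles of both curves).
#' @export
accumulation_curves <- function(table, n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(table, "gene_family_table"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  pres <- presence_matrix(table)
  g <- ncol(pres)
  if (g < 2L) stop("need >= 2 genomes for accumulation curves", call. = FALSE)
  set.seed(as.integer(seed))
  out <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(g)
    pan <- integer(g); core <- integer(g)
    cum_union <- rep(FALSE, nrow(pres))
    cum_inter <- rep(TRUE, nrow(pres))
    for (k in seq_len(g)) {
      cum_union <- cum_union | pres[, ord[k]]
      cum_inter <- cum_inter & pres[, ord[k]]
      pan[k] <- sum(cum_union)
      core[k] <- sum(cum_inter)
    }
    out[[p]] <- data.frame(permutation = p, n_genomes = seq_len(g),
                           pangenome = pan, core = core)
  }
  curves <- do.call(rbind, out)
  q <- function(v, p) unname(quantile(v, p, type = 7))
  summ <- do.call(rbind, lapply(split(curves, curves$n_genomes), function(d) {
    data.frame(n_genomes = d$n_genomes[1],
               pangenome_q1 = q(d$pangenome, .25),
               pangenome_median = q(d$pangenome, .5),
               pangenome_q3 = q(d$pangenome, .75),
               core_q1 = q(d$core, .25),
               core_median = q(d$core, .5),
               core_q3 = q(d$core, .75))
  }))
  rownames(summ) <- NULL
  list(curves = curves, summary = summ)
}

# ---- ANI and dereplication ---------------------------------------------

#' Average nucleotide identity between two genomes
#'
#' Mean pairwise alignment identity over the gene families carried by both
#' genomes (for paralogs, the best-scoring member pair), in percent.
#'
#' @param a,b `genome_record` objects.
#' @param table a `gene_family_table` covering both genomes.
#' @param config a [clustering_config()] (alignment scores / fast path).
#' @return ANI percentage.
#' @export
compute_ani <- function(a, b, table, config = clustering_config()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  m <- table$members
  fams_a <- unique(m$family[m$genome == a$strain])
  fams_b <- unique(m$family[m$genome == b$strain])
  shared <- intersect(fams_a, fams_b)
  if (length(shared) == 0L) {
    stop(sprintf("genomes %s and %s share no gene family; ANI not computable",
                 a$strain, b$strain), call. = FALSE)
  }
  seqs_a <- gene_sequences(a)
  seqs_b <- gene_sequences(b)
  ids <- vapply(shared, function(fam) {
    ga <- m$gene_id[m$family == fam & m$genome == a$strain]
    gb <- m$gene_id[m$family == fam & m$genome == b$strain]
    best <- 0
    for (x in ga) for (y in gb) {
      idcov <- .gene_identity(seqs_a[[x]], seqs_b[[y]], config)
      best <- max(best, idcov[["identity"]])
    }
    best
  }, numeric(1))
  100 * mean(ids)
}

#' All-pairs ANI matrix
#'
#' @param genomes named list of `genome_record` objects.
#' @inheritParams compute_ani
#' @return symmetric percentage matrix (diagonal 100).
#' @export
ani_matrix <- function(genomes, table, config = clustering_config()) {
  strains <- vapply(genomes, `[[`, character(1), "strain")
  n <- length(strains)
  m <- matrix(100, n, n, dimnames = list(strains, strains))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- compute_ani(genomes[[i]], genomes[[j]], table,
                                        config)
    }
  }
  m
}

#' Dereplicate near-identical genomes
#'
#' Single-linkage clusters at ANI above the threshold; one representative
#' per cluster (largest gene count, ties broken by lexicographic strain ID).
#'
#' @param genomes named list of `genome_record` objects.
#' @param config a [dereplication_config()].
#' @param table a `gene_family_table`.
#' @param clustering a [clustering_config()] for the underlying alignments.
#' @param ani optional precomputed [ani_matrix()].
#' @return list with `representatives` (strain IDs), `clusters`
#'   (data.frame strain/cluster/representative) and `ani` (matrix).
#' @export
dereplicate <- function(genomes, config = dereplication_config(), table,
                        clustering = clustering_config(), ani = NULL) {
  strains <- sort(vapply(genomes, `[[`, character(1), "strain"))
  genomes <- genomes[match(strains, vapply(genomes, `[[`, character(1),
                                           "strain"))]
  if (is.null(ani)) ani <- ani_matrix(genomes, table, clustering)
  ani <- ani[strains, strains, drop = FALSE]
  n <- length(strains)
  parent <- seq_len(n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (ani[i, j] > config$ani_threshold) {
        ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(x) .uf_find(parent, x), integer(1))
  gene_counts <- vapply(genomes, function(g) nrow(g$genes), integer(1))
  reps <- vapply(split(seq_len(n), roots), function(idx) {
    idx <- idx[order(-gene_counts[idx], strains[idx])]
    strains[idx[1]]
  }, character(1))
  cluster_id <- match(roots, sort(unique(roots)))
  clusters <- data.frame(strain = strains, cluster = cluster_id,
                         representative = unname(reps[as.character(
                           sort(unique(roots))[cluster_id])]),
                         stringsAsFactors = FALSE)
  list(representatives = sort(unname(reps)), clusters = clusters, ani = ani)
}
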