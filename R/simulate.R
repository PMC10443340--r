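#' @importFrom stats rpois runif rbinom quantile sd median setNames
#' @importFrom utils head tail
#' @import data.table
NULL

# ---- tree simulation ---------------------------------------------------

# Kingman-coalescent random binary tree over the strain labels, rescaled so
# the root-to-tip depth is exactly 1 (branch lengths are then fractions of
# the total depth and `base_subst_rate` reads as substitutions/site/depth).
.sim_strain_tree <- function(config) {
  labels <- sprintf("strain%02d", seq_len(config$n_strains))
  if (config$tree_mode == "user_newick") {
    tree <- ape::read.tree(text = config$newick)
    if (is.null(tree)) stop("invalid `newick`: could not be parsed",
                            call. = FALSE)
    if (ape::Ntip(tree) != config$n_strains) {
      stop(sprintf("invalid `newick`: has %d tips but n_strains = %d",
                   ape::Ntip(tree), config$n_strains), call. = FALSE)
    }
  } else {
    tree <- ape::rcoal(config$n_strains, tip.label = labels)
  }
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth > 0) tree$edge.length <- tree$edge.length / depth
  ape::reorder.phylo(tree, "cladewise")
}

# ---- sequence evolution ------------------------------------------------

# Evolve a sequence down the (cladewise-ordered) tree under Jukes-Cantor:
# substitution count per branch per site is Poisson(rate * branch length),
# each substitution replaces the base by one of the other three uniformly.
# Multiple hits at one site are applied sequentially. Returns a list of
# integer vectors (1..4) indexed by node id; tips are nodes 1..Ntip.
# `root_node` restricts evolution to that node's subtree (gene gain).
.evolve_nodes <- function(tree, L, rate, root_node = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(root_node)) root_node <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root_node]] <- sample.int(4L, L, replace = TRUE)
  edges <- tree$edge
  el <- tree$edge.length
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    s <- seqs[[p]]
    if (is.null(s)) next
    m <- rpois(1L, rate * L * el[i])
    if (m > 0L) {
      pos <- sample.int(L, m, replace = TRUE)
      off <- sample.int(3L, m, replace = TRUE)
      if (anyDuplicated(pos)) {
        for (j in seq_len(m)) {
          s[pos[j]] <- ((s[pos[j]] - 1L + off[j]) %% 4L) + 1L
        }
      } else {
        s[pos] <- ((s[pos] - 1L + off) %% 4L) + 1L
      }
    }
    seqs[[edges[i, 2L]]] <- s
  }
  seqs
}

.int_to_dna <- function(v) .bytes_to_string(.BASE_BYTES[v])

#' Evolve one gene alignment along a phylogeny
#'
#' Simulates a single gene of length `length` along `tree` under the
#' Jukes-Cantor model (Poisson substitution counts per branch, uniform base
#' exchange) and returns the tip sequences. Because the model is
#' substitution-only, the tip sequences are positionally aligned.
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @param length gene length in bp.
#' @param rate expected substitutions per site per unit branch length.
#' @return named character vector of tip sequences (an implicit alignment).
#' @export
evolve_alignment <- function(tree, length, rate) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  seqs <- .evolve_nodes(tree, length, rate)
  ntip <- ape::Ntip(tree)
  setNames(vapply(seqs[seq_len(ntip)], .int_to_dna, character(1)),
           tree$tip.label)
}

# 0-based polymorphic column positions among a set of equal-length sequences.
.variant_positions <- function(seqs) {
  if (length(seqs) < 2L) return(integer(0))
  m <- .byte_matrix(seqs)
  which(matrixStats_colAnyDiff(m)) - 1L
}

# column differs from its first row anywhere (base R, no extra deps)
matrixStats_colAnyDiff <- function(m) {
  colSums(m != rep(m[1L, ], each = nrow(m))) > 0L
}

# ---- pangenome simulation ----------------------------------------------

#' Simulate a strain pangenome with known truth
#'
#' Generates `n_strains` related genomes: every genome carries a mutated copy
#' of each core gene (per-gene rate classes include a fast outlier class),
#' a clade-structured subset of accessory genes created by gain/loss events
#' on the strain tree, and a fixed number of strain-unique genes. Genes are
#' laid out in randomized order on one contig per strain, separated by random
#' intergenic spacers. Alongside the genomes, complete truth tables (tree,
#' family membership, rate classes, variant site positions) are returned so
#' every downstream inference can be scored.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `genomes` (named list of `genome_record`),
#'   `truth` (class `truth_tables`) and `config`.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_strains
  lr <- config$gene_length_range

  if (n == 1L) {
    labels <- "strain01"
    tree <- NULL
  } else {
    tree <- .sim_strain_tree(config)
    labels <- tree$tip.label
  }

  fam_seqs <- list()   # family -> named character vector of carrier genes
  fam_class <- character(0)

  # core genes
  core_fams <- sprintf("core%04d", seq_len(config$n_core_genes))
  n_fast <- round(config$fast_gene_fraction * config$n_core_genes)
  fast_set <- if (n_fast > 0) sample(core_fams, n_fast) else character(0)
  for (fam in core_fams) {
    L <- sample(lr[1]:lr[2], 1L)
    rate <- config$base_subst_rate *
      if (fam %in% fast_set) config$fast_rate_multiplier else 1
    if (n == 1L) {
      tips <- setNames(.random_dna(L), labels)
    } else {
      seqs <- .evolve_nodes(tree, L, rate)
      tips <- setNames(vapply(seqs[seq_len(n)], .int_to_dna, character(1)),
                       labels)
    }
    fam_seqs[[fam]] <- tips
    fam_class[fam] <- if (fam %in% fast_set) "fast" else "normal"
  }

  # accessory genes: gain/loss events on branches; a gain inserts a fresh
  # gene at the child node (inherited by the clade), a loss removes one
  # accessory family from the clade below that branch.
  if (n > 1L && config$gain_loss_rate > 0) {
    edges <- tree$edge
    el_frac <- tree$edge.length
    ntip <- n
    node_acc <- vector("list", ntip + tree$Nnode)
    node_acc[[ntip + 1L]] <- character(0)
    acc_counter <- 0L
    acc_birth <- list()  # family -> birth node
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1L]; ch <- edges[i, 2L]
      present <- node_acc[[p]]
      # losses act per family, scaled by branch length, so a gained family's
      # survival decays smoothly with depth instead of being wiped out
      # whenever the accessory pool is small
      if (length(present) > 0L) {
        p_loss <- min(1, config$gain_loss_rate / 2 * el_frac[i])
        present <- present[runif(length(present)) >= p_loss]
      }
      n_gain <- rpois(1L, config$gain_loss_rate / 2)
      if (n_gain > 0L) {
        for (g in seq_len(n_gain)) {
          acc_counter <- acc_counter + 1L
          fam <- sprintf("acc%04d", acc_counter)
          acc_birth[[fam]] <- ch
          present <- c(present, fam)
        }
      }
      node_acc[[ch]] <- present
    }
    carriers <- lapply(setNames(names(acc_birth), names(acc_birth)),
                       function(fam) {
                         labels[vapply(seq_len(ntip), function(t)
                           fam %in% node_acc[[t]], logical(1))]
                       })
    for (fam in names(acc_birth)) {
      carr <- carriers[[fam]]
      if (length(carr) == 0L) next  # gained then lost before reaching tips
      L <- sample(lr[1]:lr[2], 1L)
      seqs <- .evolve_nodes(tree, L, config$base_subst_rate,
                            root_node = acc_birth[[fam]])
      keep <- match(carr, labels)
      tips <- setNames(vapply(seqs[keep], .int_to_dna, character(1)), carr)
      fam_seqs[[fam]] <- tips
      fam_class[fam] <- "normal"
    }
  }

  # strain-unique genes
  uniq_counter <- 0L
  for (st in labels) {
    for (j in seq_len(config$n_unique_genes_per_strain)) {
      uniq_counter <- uniq_counter + 1L
      fam <- sprintf("uniq%04d", uniq_counter)
      L <- sample(lr[1]:lr[2], 1L)
      fam_seqs[[fam]] <- setNames(.random_dna(L), st)
      fam_class[fam] <- "normal"
    }
  }

  # annotation labels: most genes are hypothetical; a slice of the unique
  # genes mimics mobile elements so the marker blacklist has work to do
  mobile <- c("transposase family protein", "phage portal protein",
              "site-specific integrase")
  fam_product <- setNames(rep("hypothetical protein", length(fam_seqs)),
                          names(fam_seqs))
  uniq_fams <- grep("^uniq", names(fam_seqs), value = TRUE)
  if (length(uniq_fams) > 0) {
    is_mobile <- runif(length(uniq_fams)) < 0.15
    if (any(is_mobile)) {
      fam_product[uniq_fams[is_mobile]] <-
        sample(mobile, sum(is_mobile), replace = TRUE)
    }
  }

  # assemble one contig per strain: randomized gene order, random spacers
  genomes <- list()
  for (st in labels) {
    fams <- names(fam_seqs)[vapply(fam_seqs, function(s) st %in% names(s),
                                   logical(1))]
    fams <- fams[sample.int(length(fams))]
    gseqs <- vapply(fams, function(f) fam_seqs[[f]][[st]], character(1))
    spacer_n <- config$intergenic_spacer
    pieces <- character(2L * length(fams) + 1L)
    starts <- integer(length(fams))
    pos <- 0L
    for (i in seq_along(fams)) {
      sp <- if (spacer_n > 0) .random_dna(spacer_n) else ""
      pieces[2L * i - 1L] <- sp
      pieces[2L * i] <- gseqs[i]
      pos <- pos + spacer_n
      starts[i] <- pos + 1L
      pos <- pos + nchar(gseqs[i])
    }
    pieces[2L * length(fams) + 1L] <-
      if (spacer_n > 0) .random_dna(spacer_n) else ""
    contig_name <- paste0(st, "_contig1")
    contig <- paste(pieces, collapse = "")
    genes <- data.frame(
      gene_id = paste(st, fams, sep = "_"),
      family = fams,
      contig = contig_name,
      start = starts,
      end = starts + nchar(gseqs) - 1L,
      strand = "+",
      length = nchar(gseqs),
      product = unname(fam_product[fams]),
      stringsAsFactors = FALSE
    )
    genomes[[st]] <- structure(
      list(strain = st, contigs = setNames(contig, contig_name),
           genes = genes),
      class = "genome_record")
  }

  genomes <- genomes[sort(labels)]

  gft <- do.call(rbind, lapply(names(fam_seqs), function(fam) {
    carr <- names(fam_seqs[[fam]])
    data.frame(family = fam, genome = carr,
               gene_id = paste(carr, fam, sep = "_"),
               stringsAsFactors = FALSE)
  }))
  variant_sites <- lapply(fam_seqs, .variant_positions)

  truth <- structure(list(
    true_tree = tree,
    gene_family_truth = gft,
    per_gene_rate_class = data.frame(family = names(fam_class),
                                     class = unname(fam_class),
                                     stringsAsFactors = FALSE),
    true_variant_sites = variant_sites
  ), class = "truth_tables")

  list(genomes = genomes, truth = truth, config = config)
}

#' Extract gene sequences from a genome record
#'
#' @param genome a `genome_record`.
#' @param gene_ids optional subset of gene IDs.
#' @return named character vector of gene nucleotide sequences (forward
#'   strand as annotated).
#' @export
gene_sequences <- function(genome, gene_ids = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes
  if (!is.null(gene_ids)) {
    g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
    if (anyNA(g$gene_id)) stop("unknown gene_id(s) requested", call. = FALSE)
  }
  out <- substring(genome$contigs[g$contig], g$start, g$end)
  rc <- g$strand == "-"
  if (any(rc)) out[rc] <- .revcomp(out[rc])
  setNames(out, g$gene_id)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d genes, %s bp\n",
              x$strain, length(x$contigs), nrow(x$genes),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

# ---- read simulation ---------------------------------------------------

#' Simulate shotgun reads from a strain mixture
#'
#' Draws `n_reads` single-end reads: the source strain is chosen by the
#' mixture proportions, the position uniformly over valid start positions of
#' that strain's contigs, and the strand with probability 1/2. Per-base
#' substitution errors are applied at `error_rate`. Each read carries its
#' truth label (source strain, contig, position, strand).
#'
#' @param genomes named list of `genome_record` objects.
#' @param proportions numeric mixture weights, one per genome, summing to 1.
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return object of class `read_set`: a list with `reads` (data.frame
#'   read_id, seq, strain, contig, start, strand), `proportions`,
#'   `read_length`, `error_rate`, `seed`.
#' @export
simulate_reads <- function(genomes, proportions, n_reads, read_length,
                           error_rate = 0, seed = 1L) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  strains <- names(genomes)
  .check_field(length(proportions) == length(genomes), "proportions",
               "must have one weight per genome")
  .check_field(all(proportions >= 0) && abs(sum(proportions) - 1) < 1e-9,
               "proportions", "must be non-negative and sum to 1")
  .check_scalar_number(n_reads, "n_reads", min = 1, integer = TRUE)
  .check_scalar_number(read_length, "read_length", min = 1, integer = TRUE)
  .check_scalar_number(error_rate, "error_rate", min = 0, max = 1)
  for (i in which(proportions > 0)) {
    if (all(nchar(genomes[[i]]$contigs) < read_length)) {
      stop(sprintf("read_length %d exceeds every contig of strain %s",
                   read_length, strains[i]), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  src <- sample.int(length(genomes), n_reads, replace = TRUE,
                    prob = proportions)
  seqs <- character(n_reads)
  contig_lab <- character(n_reads)
  start <- integer(n_reads)
  for (i in unique(src)) {
    idx <- which(src == i)
    contigs <- genomes[[i]]$contigs
    contigs <- contigs[nchar(contigs) >= read_length]
    npos <- nchar(contigs) - read_length + 1L
    ci <- if (length(contigs) == 1L) rep(1L, length(idx)) else
      sample.int(length(contigs), length(idx), replace = TRUE,
                 prob = npos)
    st <- floor(runif(length(idx)) * npos[ci]) + 1L
    seqs[idx] <- substring(contigs[ci], st, st + read_length - 1L)
    contig_lab[idx] <- names(contigs)[ci]
    start[idx] <- st
  }
  flip <- runif(n_reads) < 0.5
  if (any(flip)) {
    seqs[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
  }
  if (error_rate > 0) {
    nerr <- rbinom(n_reads, read_length, error_rate)
    for (i in which(nerr > 0L)) {
      b <- as.integer(charToRaw(seqs[i]))
      pos <- sample.int(read_length, nerr[i])
      cur <- match(b[pos], .BASE_BYTES)
      off <- sample.int(3L, nerr[i], replace = TRUE)
      b[pos] <- .BASE_BYTES[((cur - 1L + off) %% 4L) + 1L]
      seqs[i] <- .bytes_to_string(b)
    }
  }
  structure(list(
    reads = data.frame(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      seq = seqs,
      strain = strains[src],
      contig = contig_lab,
      start = start,
      strand = ifelse(flip, "-", "+"),
      stringsAsFactors = FALSE),
    proportions = setNames(as.numeric(proportions), strains),
    read_length = as.integer(read_length),
    error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "read_set")
}
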