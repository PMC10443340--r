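#' Simulation configuration
#'
#' Parameters of the synthetic pangenome and read-mixture generator. Defaults
#' describe a desk-scale *Lactobacillus crispatus*-like collection: 22 strains
#' (a typical dereplicated representative set), several hundred core genes of
#' roughly 0.6--1.5 kb, about 2\% core nucleotide divergence accumulated over
#' the tree depth, a small fraction (5\%) of "fast" genes evolving an order of
#' magnitude quicker (the highly-variable-gene signal), gene gain/loss
#' producing accessory families, a dozen strain-unique genes per genome, and
#' 150 bp shotgun reads.
#'
#' @param n_strains number of strain genomes to simulate (>= 1).
#' @param tree_mode `"random_coalescent"` for a Kingman-coalescent random
#'   binary tree (rescaled to root-to-tip depth 1) or `"user_newick"` to
#'   supply `newick`.
#' @param newick Newick string used when `tree_mode = "user_newick"`.
#' @param n_core_genes number of core gene families (>= 1).
#' @param gene_length_range two-element bp interval genes are drawn from.
#' @param base_subst_rate expected substitutions per site along the total
#'   (root-to-tip) tree depth for a normal-rate gene.
#' @param fast_gene_fraction proportion of core genes in the fast rate class,
#'   in \[0, 1\].
#' @param fast_rate_multiplier rate multiplier (>= 1) applied to fast genes.
#' @param gain_loss_rate expected accessory gain + loss events per branch.
#' @param n_unique_genes_per_strain strain-unique genes planted per genome.
#' @param intergenic_spacer bp of random intergenic sequence between genes.
#' @param read_length simulated read length in bp.
#' @param error_rate per-base substitution error probability for reads.
#' @param seed integer seed; identical configs reproduce identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_strains = 22L,
                              tree_mode = c("random_coalescent", "user_newick"),
                              newick = NULL,
                              n_core_genes = 500L,
                              gene_length_range = c(600L, 1500L),
                              base_subst_rate = 0.02,
                              fast_gene_fraction = 0.05,
                              fast_rate_multiplier = 10,
                              gain_loss_rate = 2,
                              n_unique_genes_per_strain = 12L,
                              intergenic_spacer = 200L,
                              read_length = 150L,
                              error_rate = 0,
                              seed = 1L) {
  tree_mode <- match.arg(tree_mode)
  .check_scalar_number(n_strains, "n_strains", min = 1, integer = TRUE)
  .check_scalar_number(n_core_genes, "n_core_genes", min = 1, integer = TRUE)
  .check_field(is.numeric(gene_length_range) && length(gene_length_range) == 2L &&
                 all(gene_length_range >= 9) &&
                 gene_length_range[1] <= gene_length_range[2],
               "gene_length_range", "must be an increasing bp interval >= 9")
  .check_scalar_number(base_subst_rate, "base_subst_rate", min = 0)
  .check_scalar_number(fast_gene_fraction, "fast_gene_fraction", min = 0, max = 1)
  .check_scalar_number(fast_rate_multiplier, "fast_rate_multiplier", min = 1)
  .check_scalar_number(gain_loss_rate, "gain_loss_rate", min = 0)
  .check_scalar_number(n_unique_genes_per_strain, "n_unique_genes_per_strain",
                       min = 0, integer = TRUE)
  .check_scalar_number(intergenic_spacer, "intergenic_spacer", min = 0,
                       integer = TRUE)
  .check_scalar_number(read_length, "read_length", min = 1, integer = TRUE)
  .check_scalar_number(error_rate, "error_rate", min = 0, max = 1)
  .check_scalar_number(seed, "seed", integer = TRUE)
  if (tree_mode == "user_newick") {
    .check_field(is.character(newick) && length(newick) == 1L, "newick",
                 "must be a single Newick string when tree_mode = 'user_newick'")
  }
  structure(list(
    n_strains = as.integer(n_strains), tree_mode = tree_mode, newick = newick,
    n_core_genes = as.integer(n_core_genes),
    gene_length_range = as.integer(gene_length_range),
    base_subst_rate = base_subst_rate,
    fast_gene_fraction = fast_gene_fraction,
    fast_rate_multiplier = fast_rate_multiplier,
    gain_loss_rate = gain_loss_rate,
    n_unique_genes_per_strain = as.integer(n_unique_genes_per_strain),
    intergenic_spacer = as.integer(intergenic_spacer),
    read_length = as.integer(read_length),
    error_rate = error_rate, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Gene clustering configuration
#'
#' Thresholds for building the orthologous gene family (COG) graph: an edge
#' joins two genes when their global alignment reaches `min_identity` over at
#' least `min_coverage` of the longer sequence. Families are the connected
#' components of this graph.
#'
#' @param min_identity minimum alignment identity (matches / aligned columns,
#'   end gaps excluded), default 0.50.
#' @param min_coverage minimum aligned span as a fraction of the longer
#'   sequence, default 0.80.
#' @param match,mismatch,gap_opening,gap_extension dynamic-programming
#'   alignment scores (gap penalties are positive costs).
#' @param prefilter_k k-mer length of the shared-k-mer candidate prefilter.
#' @param prefilter_stride stride at which k-mers are enumerated (default 1,
#'   exhaustive; larger strides trade sensitivity on divergent pairs for
#'   speed).
#' @param fast_path skip the DP alignment for equal-length pairs already
#'   decided by ungapped identity (exact on indel-free data).
#' @return an object of class `clustering_config`.
#' @export
clustering_config <- function(min_identity = 0.50, min_coverage = 0.80,
                              match = 2, mismatch = -3,
                              gap_opening = 5, gap_extension = 2,
                              prefilter_k = 15L, prefilter_stride = 1L,
                              fast_path = TRUE) {
  .check_field(min_identity > 0 && min_identity <= 1, "min_identity",
               "must be in (0, 1]")
  .check_field(min_coverage > 0 && min_coverage <= 1, "min_coverage",
               "must be in (0, 1]")
  .check_scalar_number(match, "match", min = 0)
  .check_scalar_number(mismatch, "mismatch", max = 0)
  .check_scalar_number(gap_opening, "gap_opening", min = 0)
  .check_scalar_number(gap_extension, "gap_extension", min = 0)
  .check_scalar_number(prefilter_k, "prefilter_k", min = 4, integer = TRUE)
  .check_scalar_number(prefilter_stride, "prefilter_stride", min = 1,
                       integer = TRUE)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 match = match, mismatch = mismatch,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 prefilter_k = as.integer(prefilter_k),
                 prefilter_stride = as.integer(prefilter_stride),
                 fast_path = isTRUE(fast_path)),
            class = "clustering_config")
}

#' SNP calling configuration
#'
#' An alignment column is a SNP site when at least two bases occur and the
#' summed occurrence of all non-majority bases reaches `min_occurrence` of the
#' genome collection; the occurrence filter suppresses singleton alleles that
#' are more likely sequencing/assembly errors than real variants.
#'
#' @param min_occurrence minimum summed proportion of genomes carrying a
#'   non-majority allele, default 0.20.
#' @param drop_gap_columns drop columns containing any gap before calling
#'   (SNPs are substitutions only), default TRUE.
#' @return an object of class `snp_calling_config`.
#' @export
snp_calling_config <- function(min_occurrence = 0.20, drop_gap_columns = TRUE) {
  .check_field(is.numeric(min_occurrence) && length(min_occurrence) == 1L &&
                 min_occurrence >= 0 && min_occurrence <= 1,
               "min_occurrence", "must be in [0, 1]")
  structure(list(min_occurrence = min_occurrence,
                 drop_gap_columns = isTRUE(drop_gap_columns)),
            class = "snp_calling_config")
}

#' Dereplication configuration
#'
#' @param ani_threshold average nucleotide identity percentage above which two
#'   genomes are considered redundant (default 99).
#' @return an object of class `dereplication_config`.
#' @export
dereplication_config <- function(ani_threshold = 99) {
  .check_field(is.numeric(ani_threshold) && length(ani_threshold) == 1L &&
                 ani_threshold > 0 && ani_threshold <= 100,
               "ani_threshold", "must be in (0, 100]")
  structure(list(ani_threshold = ani_threshold),
            class = "dereplication_config")
}

#' Marker gene filter configuration
#'
#' Filters applied to strain-unique gene families when selecting
#' strain-specific marker genes: no cross-genome similarity hit (seeded by a
#' shared k-mer, confirmed by local alignment of at least `l_min` bp at
#' `id_min` identity), no mobile-element annotation, not within
#' `end_distance` bp of a contig end.
#'
#' @param end_distance minimum distance (bp) of a marker from a contig end.
#' @param blacklist annotation keywords that disqualify a candidate.
#' @param l_min minimum local alignment length (bp) for a cross-genome hit.
#' @param id_min minimum identity of a disqualifying cross-genome hit.
#' @param k seed k-mer length for the cross-genome similarity scan.
#' @param max_markers maximum markers kept per strain (longest first).
#' @param ani_warn_threshold warn when two profiled strains exceed this ANI
#'   percentage (multi-mapping risk), default 98.
#' @return an object of class `marker_filter_config`.
#' @export
marker_filter_config <- function(end_distance = 500L,
                                 blacklist = c("transposase", "phage",
                                               "integrase"),
                                 l_min = 100L, id_min = 0.90, k = 21L,
                                 max_markers = 10L, ani_warn_threshold = 98) {
  .check_scalar_number(end_distance, "end_distance", min = 0, integer = TRUE)
  .check_field(is.character(blacklist), "blacklist",
               "must be a character vector of keywords")
  .check_scalar_number(l_min, "l_min", min = 1, integer = TRUE)
  .check_field(id_min > 0 && id_min <= 1, "id_min", "must be in (0, 1]")
  .check_scalar_number(k, "k", min = 8, integer = TRUE)
  .check_scalar_number(max_markers, "max_markers", min = 1, integer = TRUE)
  .check_scalar_number(ani_warn_threshold, "ani_warn_threshold",
                       min = 0, max = 100)
  structure(list(end_distance = as.integer(end_distance),
                 blacklist = blacklist, l_min = as.integer(l_min),
                 id_min = id_min, k = as.integer(k),
                 max_markers = as.integer(max_markers),
                 ani_warn_threshold = ani_warn_threshold),
            class = "marker_filter_config")
}
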