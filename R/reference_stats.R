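# Published reference statistics for the L. crispatus genome collection,
# used to sanity-check the pipeline's bookkeeping arithmetic (core/pangenome
# percentage, non-synonymous percentage, genome-size summary). These are
# inputs, not results: the package recomputes every derived quantity.

#' Reference summary statistics for the *L. crispatus* collection
#'
#' Headline counts reported for the 22-strain representative
#' *Lactobacillus crispatus* genome collection: pangenome and core COG
#' counts, the cgSNP totals between the two most divergent co-cultured
#' strains with their non-synonymous fraction, the core-genome SNP rate, the
#' HVG count, and the size of the concatenated core gene set. Used by the
#' consistency checks that verify the package's summary arithmetic
#' reproduces the published ratios from the published counts.
#'
#' @return named list of reference counts.
#' @export
crispatus_reference_stats <- function() {
  list(
    n_genomes = 22L,
    pangenome_cogs = 6512L,
    core_cogs = 959L,
    core_pct_printed = 15,
    unique_genes_per_genome_mean = 157.3,
    unique_genes_per_genome_sd = 54.3,
    core_concat_bp = 904903,
    mean_cgsnps_vs_reference = 15007,
    snps_per_mbp = 364.7,
    n_hvgs = 52L,
    hvg_mean_snps_max = 347.45,
    hvg_mean_snps_min = 90.25,
    pair_cgsnps_total = 27906L,
    pair_cgsnps_nonsyn = 8238L,
    nonsyn_pct_printed = 29,
    mean_genome_size_mbp_printed = 2.20
  )
}

#' Genome features of the 22 representative *L. crispatus* assemblies
#'
#' Reads the bundled table of assembly accession, strain name, genome size
#' (Mbp), CDS count, completeness and isolation source for the 22
#' representative genomes (public NCBI assembly metadata).
#'
#' @return data.frame with 22 rows.
#' @export
crispatus_genome_table <- function() {
  path <- system.file("extdata", "crispatus_representative_genomes.tsv",
                      package = "panmicrodiv", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
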