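# End-to-end orchestration over simulator output: each stage writes its
# analytic TSV/Newick artifacts into the run directory plus a JSON manifest
# (resolved config, derived stage seeds, input checksums, timestamps).
# Re-running with the same config and seed reproduces byte-identical
# analytic outputs; only the manifest timestamps differ.

#' Run the full micro-diversity pipeline on a simulated community
#'
#' Chains the stages end-to-end: simulate -> pangenome (families, partition,
#' accumulation curves, ANI, dereplication) -> core SNPs (occurrence filter,
#' SNPs/Mbp, syn/nonsyn summary) -> per-gene variability + HVGs -> NJ trees
#' (full core and HVG-restricted, bootstrap) -> marker selection -> mixture
#' profiling over the time points.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created; analytic outputs write-once).
#' @param stages subset of
#'   `c("simulate","pangenome","core-snps","hvg","tree","markers","profile")`;
#'   later stages require the earlier ones in the same call.
#' @param clustering a [clustering_config()].
#' @param snp a [snp_calling_config()].
#' @param filters a [marker_filter_config()].
#' @param derep a [dereplication_config()].
#' @param mixture named list describing the profiled community:
#'   `n_strains` (strains in the mixture, taken as the most divergent
#'   leaves), `proportions` (per time point, rows of a matrix or a single
#'   vector reused), `time_points`, `n_reads` per time point.
#' @param n_bootstrap bootstrap replicates for the core tree.
#' @param n_permutations permutations for the accumulation curves.
#' @param use_truth_families skip clustering and take the simulator's truth
#'   families (fast; default FALSE).
#' @return invisibly, a list of in-memory stage results (also all written
#'   under `out_dir`).
#' @export
run_pipeline <- function(config = simulation_config(),
                         out_dir,
                         stages = c("simulate", "pangenome", "core-snps",
                                    "hvg", "tree", "markers", "profile"),
                         clustering = clustering_config(),
                         snp = snp_calling_config(),
                         filters = marker_filter_config(),
                         derep = dereplication_config(),
                         mixture = list(n_strains = 4L,
                                        proportions = c(0.5, 0.3, 0.15, 0.05),
                                        time_points = c(10, 24, 48),
                                        n_reads = 100000L),
                         n_bootstrap = 100L,
                         n_permutations = 50L,
                         use_truth_families = FALSE) {
  known <- c("simulate", "pangenome", "core-snps", "hvg", "tree", "markers",
             "profile")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  res <- list()
  warnings_log <- character(0)

  withCallingHandlers({

  # ---- simulate ----
  message(sprintf("[simulate] %d strains, %d core genes, seed %d",
                  config$n_strains, config$n_core_genes, config$seed))
  sim <- simulate_pangenome(config)
  res$sim <- sim
  if ("simulate" %in% stages) {
    gdir <- file.path(out_dir, "genomes")
    for (g in sim$genomes) write_genome(g, gdir)
    write_truth(sim, file.path(out_dir, "truth"))
  }

  strains <- names(sim$genomes)
  reference <- NULL

  # ---- pangenome ----
  if (any(c("pangenome", "core-snps", "hvg", "tree", "markers", "profile")
          %in% stages)) {
    if (use_truth_families) {
      table <- gene_family_table(sim$truth$gene_family_truth, strains)
    } else {
      table <- cluster_gene_families(sim$genomes, clustering)
    }
    res$table <- table
    part <- classify_families(table)
    res$partition <- part
    message(sprintf("[pangenome] %d families: %d core / %d accessory / %d unique",
                    nrow(table$counts), length(part$core),
                    length(part$accessory), length(part$unique)))
    if ("pangenome" %in% stages) {
      .write_tsv(table$members, file.path(out_dir, "family_members.tsv"))
      pm <- data.frame(family = rownames(table$counts), table$counts,
                       check.names = FALSE)
      .write_tsv(pm, file.path(out_dir, "presence_absence.tsv"))
      .write_tsv(part$summary, file.path(out_dir, "partition_summary.tsv"))
      .write_tsv(data.frame(strain = names(part$unique_counts),
                            unique_genes = unname(part$unique_counts)),
                 file.path(out_dir, "unique_gene_counts.tsv"))
      if (length(strains) >= 2L) {
        acc <- accumulation_curves(table, n_permutations,
                                   seed = .stage_seed(config$seed, "accumulation"))
        .write_tsv(acc$summary, file.path(out_dir, "accumulation_curves.tsv"))
        res$accumulation <- acc
      }
    }
  }

  # ---- core alignments, reference, SNPs ----
  if (any(c("core-snps", "hvg", "tree", "markers", "profile") %in% stages)) {
    aln <- build_core_alignments(table, sim$genomes,
                                 families = part$core,
                                 reference = strains[1L],
                                 config = clustering)
    concat <- concat_alignments(aln)
    D_full <- p_distance_matrix(concat)
    reference <- select_reference_strain(D_full)
    message(sprintf("[core-snps] reference strain (most divergent): %s",
                    reference))
    res$reference <- reference
    res$alignments <- aln
    res$concat <- concat
    snp_sites <- do.call(rbind, c(lapply(aln, extract_snp_sites, config = snp),
                                  list(make.row.names = FALSE)))
    res$snp_sites <- snp_sites
    aln_len <- nchar(concat$seqs[[1]])
    mean_genome_len <- mean(vapply(sim$genomes, function(g)
      sum(nchar(g$contigs)), numeric(1)))
    rate_aln <- snps_per_mbp(nrow(snp_sites), aln_len)
    rate_gen <- snps_per_mbp(nrow(snp_sites), mean_genome_len)
    summ <- genomewide_snp_summary(aln, reference)
    res$snp_summary <- summ
    message(sprintf(
      "[core-snps] %d SNP sites over %d aligned bp (%.1f SNPs/Mbp of alignment)",
      nrow(snp_sites), aln_len, rate_aln))
    if ("core-snps" %in% stages) {
      .write_tsv(snp_sites, file.path(out_dir, "snp_sites.tsv"))
      .write_tsv(reference_variant_table(aln, snp_sites, reference),
                 file.path(out_dir, "ref_variants.tsv"))
      .write_tsv(summ$per_genome, file.path(out_dir, "snp_summary.tsv"))
      .write_tsv(data.frame(
        n_snp_sites = nrow(snp_sites),
        alignment_bp = aln_len,
        mean_genome_bp = mean_genome_len,
        snps_per_mbp_alignment = rate_aln,
        snps_per_mbp_genome = rate_gen),
        file.path(out_dir, "snp_rates.tsv"))
    }
  }

  # ---- per-gene variability and HVGs ----
  if (any(c("hvg", "tree", "markers", "profile") %in% stages)) {
    stats <- per_gene_snp_stats(aln, reference)
    stats <- classify_variability(stats)
    hv <- detect_hvgs(stats)
    res$gene_stats <- stats
    res$hvgs <- hv
    message(sprintf("[hvg] %d HVGs above cutoff %.2f (Q3 %.2f, Q1 %.2f)",
                    length(hv$hvgs), hv$cutoff, hv$q3, hv$q1))
    if ("hvg" %in% stages) {
      .write_tsv(stats, file.path(out_dir, "gene_variability.tsv"))
      .write_tsv(data.frame(family = hv$hvgs,
                            cutoff = hv$cutoff),
                 file.path(out_dir, "hvg_list.tsv"))
    }
  }

  # ---- trees ----
  if ("tree" %in% stages && length(strains) >= 4L) {
    boot <- bootstrap_support(concat, n_replicates = n_bootstrap,
                              seed = .stage_seed(config$seed, "bootstrap"))
    ape::write.tree(boot, file.path(out_dir, "core_tree.nwk"))
    res$core_tree <- boot
    if (length(hv$hvgs) > 0L) {
      htree <- hvg_tree(aln, hv$hvgs)
      ape::write.tree(htree, file.path(out_dir, "hvg_tree.nwk"))
      res$hvg_tree <- htree
    }
    dm <- data.frame(genome = rownames(D_full), D_full, check.names = FALSE)
    .write_tsv(dm, file.path(out_dir, "p_distance.tsv"))
    message(sprintf("[tree] core NJ tree with %d bootstrap replicates",
                    n_bootstrap))
  }

  # ---- markers and profiling ----
  if (any(c("markers", "profile") %in% stages)) {
    mix_n <- min(mixture$n_strains, length(strains))
    mean_d <- rowSums(D_full) / (nrow(D_full) - 1L)
    mix_strains <- rownames(D_full)[order(-mean_d,
                                          rownames(D_full))][seq_len(mix_n)]
    mix_genomes <- sim$genomes[mix_strains]
    sub_table <- gene_family_table(
      table$members[table$members$genome %in% mix_strains, , drop = FALSE],
      sort(mix_strains))
    markers <- select_marker_genes(sub_table, mix_genomes, filters)
    res$markers <- markers
    message(sprintf("[markers] %d markers over %d strains (%d candidates audited)",
                    nrow(markers$markers), length(unique(markers$markers$strain)),
                    nrow(markers$audit)))
    if ("markers" %in% stages) {
      .write_tsv(markers$markers[, c("strain", "gene_id", "length")],
                 file.path(out_dir, "markers.tsv"))
      .write_tsv(markers$audit, file.path(out_dir, "marker_audit.tsv"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(markers$markers$seq,
                                          markers$markers$gene_id)),
        file.path(out_dir, "markers.fna"), width = 80L)
    }

    if ("profile" %in% stages) {
      props <- mixture$proportions
      if (is.null(dim(props))) {
        props <- matrix(rep(props, length(mixture$time_points)),
                        nrow = length(mixture$time_points), byrow = TRUE)
      }
      stopifnot(ncol(props) == length(mix_strains))
      read_sets <- list()
      truth_prop <- list()
      for (ti in seq_along(mixture$time_points)) {
        tp <- as.character(mixture$time_points[ti])
        rs <- simulate_reads(mix_genomes, props[ti, ], mixture$n_reads,
                             config$read_length, config$error_rate,
                             seed = .stage_seed(config$seed,
                                                paste0("reads", tp)))
        write_fastq(rs, file.path(out_dir, "reads",
                                  paste0("t", tp, ".fastq")))
        read_sets[[tp]] <- rs
        truth_prop[[tp]] <- data.frame(time = tp, strain = mix_strains,
                                       proportion = props[ti, ],
                                       stringsAsFactors = FALSE)
      }
      prof <- profile_timeseries(read_sets, markers)
      res$profile <- prof
      res$mixture_truth <- do.call(rbind, c(truth_prop,
                                            list(make.row.names = FALSE)))
      .write_tsv(prof$profile, file.path(out_dir, "abundance_profile.tsv"))
      .write_tsv(prof$library, file.path(out_dir, "library_stats.tsv"))
      .write_tsv(res$mixture_truth, file.path(out_dir,
                                              "mixture_truth.tsv"))
      message(sprintf("[profile] %d time points x %d strains profiled",
                      length(read_sets), length(mix_strains)))
    }
  }

  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # ---- manifest ----
  outputs <- setdiff(list.files(out_dir, recursive = TRUE),
                     "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    tool = "panmicrodiv",
    version = as.character(utils::packageVersion("panmicrodiv")),
    stages = stages,
    config = unclass(config),
    stage_seeds = list(
      accumulation = .stage_seed(config$seed, "accumulation"),
      bootstrap = .stage_seed(config$seed, "bootstrap")),
    warnings = warnings_log,
    outputs = as.list(setNames(unname(checksums), outputs)),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}
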