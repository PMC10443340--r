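#!/usr/bin/env Rscript
# Stage 4 -- per-gene variability, HVGs and phylogenomic trees.
#
# Computes per-core-gene SNP statistics against the reference, flags the
# highly variable genes by the Q3 + 1.5*IQR rule and the conserved genes
# below Q1, then builds the bootstrapped neighbour-joining core tree and
# the HVG-restricted tree and compares both against the simulated truth.

suppressMessages(library(panmicrodiv))

gdir <- "scratch/sim/genomes"
out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
fastas <- sort(list.files(gdir, pattern = "\\.fna$", full.names = TRUE))
genomes <- lapply(fastas, function(fa)
  read_genome(fa, sub("\\.fna$", ".gff3", fa)))
names(genomes) <- vapply(genomes, `[[`, character(1), "strain")
members <- read.delim("scratch/pangenome/family_members.tsv")
tab <- gene_family_table(members, sort(names(genomes)))
core <- classify_families(tab)$core
aln <- build_core_alignments(tab, genomes, families = core,
                             reference = names(genomes)[1])
concat <- concat_alignments(aln)
reference <- select_reference_strain(p_distance_matrix(concat))

stats <- classify_variability(per_gene_snp_stats(aln, reference))
hv <- detect_hvgs(stats)
cons <- conserved_genes(stats)
message(sprintf("per-gene mean SNPs vs %s: %.1f-%.1f (median %.1f)",
                reference, min(stats$mean_snps), max(stats$mean_snps),
                median(stats$mean_snps)))
message(sprintf("%d HVGs above Q3 + 1.5*IQR = %.2f; %d conserved genes below Q1 = %.2f",
                length(hv$hvgs), hv$cutoff, length(cons), hv$q1))

# how well does the IQR rule find the planted fast class?
rate_class <- read.delim("scratch/sim/truth/per_gene_rate_class.tsv")
# recovered family IDs are the lexicographically smallest member gene IDs;
# map them back to the simulator's family labels via the member table
fam_of <- function(ids) unique(sub("^strain[0-9]+_", "", ids))
hv_truth <- sub("^strain[0-9]+_", "", hv$hvgs)
fast <- rate_class$family[rate_class$class == "fast"]
fast_core <- intersect(fast, sub("^strain[0-9]+_", "", stats$family))
message(sprintf("planted fast genes recovered: %d/%d (false positives: %d)",
                length(intersect(hv_truth, fast)), length(fast_core),
                length(setdiff(hv_truth, fast))))

write.table(stats, file.path(out, "gene_variability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(c(sprintf("# HVG cutoff (Q3 + 1.5*IQR): %.4f", hv$cutoff),
             hv$hvgs), file.path(out, "hvg_list.tsv"))

boot <- bootstrap_support(concat, n_replicates = 200, seed = 13)
ape::write.tree(boot, file.path(out, "core_tree.nwk"))
truth_tree <- ape::read.tree("scratch/sim/truth/true_tree.nwk")
rf <- ape::dist.topo(ape::unroot(truth_tree), boot)
message(sprintf("core NJ tree vs true coalescent tree: Robinson-Foulds = %d",
                as.integer(rf)))
sup <- attr(boot, "support")$support
message(sprintf("bootstrap support (200 replicates): %d/%d splits >= 50%%",
                sum(sup >= 50), length(sup)))

ht <- hvg_tree(aln, hv$hvgs)
ape::write.tree(ht, file.path(out, "hvg_tree.nwk"))
message(sprintf("HVG tree (from %d genes) vs core tree: Robinson-Foulds = %d",
                length(hv$hvgs), as.integer(ape::dist.topo(ht, boot))))
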