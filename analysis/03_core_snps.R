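#!/usr/bin/env Rscript
# Stage 3 -- core-genome SNP profiling.
#
# Builds per-family core alignments, picks the most divergent strain as
# reference, extracts occurrence-filtered SNP sites (>= 20% of genomes must
# carry a non-majority allele), normalises to SNPs/Mbp under both
# denominator conventions, and tallies synonymous vs non-synonymous
# substitutions against the reference.

suppressMessages(library(panmicrodiv))

gdir <- "scratch/sim/genomes"
out <- "results/core_snps"
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
D <- p_distance_matrix(concat)
reference <- select_reference_strain(D)
message(sprintf("reference strain (deepest split): %s", reference))

snp_sites <- do.call(rbind, lapply(aln, extract_snp_sites))
aln_bp <- nchar(concat$seqs[[1]])
mean_genome_bp <- mean(vapply(genomes, function(g)
  sum(nchar(g$contigs)), numeric(1)))
message(sprintf("%d occurrence-filtered SNP sites over %d core-alignment bp",
                nrow(snp_sites), aln_bp))
message(sprintf("SNPs/Mbp: %.1f (alignment denominator) / %.1f (mean genome length denominator)",
                snps_per_mbp(nrow(snp_sites), aln_bp),
                snps_per_mbp(nrow(snp_sites), mean_genome_bp)))

summ <- genomewide_snp_summary(aln, reference)
message(sprintf("mean cgSNPs vs reference: %.0f; overall %d%% of coding SNPs non-synonymous",
                mean(summ$per_genome$snps), summ$total$pct_nonsyn))

write.table(snp_sites, "scratch/snp_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$per_genome, file.path(out, "snp_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(genome = rownames(D), round(D, 6),
                       check.names = FALSE),
            file.path(out, "p_distance.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
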