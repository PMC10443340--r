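#!/usr/bin/env Rscript
# Stage 1 -- simulate the study community.
#
# Generates the desk-scale stand-in for the 22-strain L. crispatus
# collection: a coalescent strain tree, 300 core genes (5% of them in the
# fast class that the HVG analysis is meant to find), clade-structured
# accessory genes and a dozen strain-unique genes per genome. Writes
# FASTA + GFF3 per strain and the full truth tables.

suppressMessages(library(panmicrodiv))

out <- "scratch/sim"
cfg <- simulation_config(n_strains = 22, n_core_genes = 300, seed = 2024)
message(sprintf("simulating %d strains x %d core genes (seed %d)",
                cfg$n_strains, cfg$n_core_genes, cfg$seed))
sim <- simulate_pangenome(cfg)
for (g in sim$genomes) write_genome(g, file.path(out, "genomes"))
write_truth(sim, file.path(out, "truth"))

sizes <- vapply(sim$genomes, function(g) sum(nchar(g$contigs)), numeric(1))
n_genes <- vapply(sim$genomes, function(g) nrow(g$genes), numeric(1))
message(sprintf("genome sizes: %.0f-%.0f kb (mean %.0f kb), %d-%d genes",
                min(sizes) / 1e3, max(sizes) / 1e3, mean(sizes) / 1e3,
                min(n_genes), max(n_genes)))
rate_tab <- table(sim$truth$per_gene_rate_class$class)
message(sprintf("planted rate classes: %d normal, %d fast",
                rate_tab[["normal"]], rate_tab[["fast"]]))
message("wrote ", out)
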