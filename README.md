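# panmicrodiv

Strain-level micro-diversity analysis for bacterial genome collections,
built around the comparative-genomics workflow used to dissect
*Lactobacillus crispatus* — the dominant, health-associated colonizer of
the human vaginal tract whose strains differ markedly in competitive
ability. The package is aimed at microbial comparative genomicists who
have a set of conspecific genomes (and optionally shotgun reads from
defined co-cultures) and want to go from sequences to pangenome structure,
core-genome SNP profiles, fast-evolving genes, phylogenomic trees and
strain abundances with every step testable against simulated truth.

## The analysis in brief

* **Pangenome**: genes are clustered into orthologous families (COGs) by
  global alignment at ≥ 50% identity over ≥ 80% of the longer sequence;
  families are connected components of the resulting graph. Families
  present in all genomes form the **core genome**, families in exactly one
  genome are **strain-unique**; accumulation curves over random genome
  orderings diagnose an open pangenome.
* **cgSNPs**: on per-family core alignments, a column is a SNP site iff at
  least two bases occur and non-majority alleles reach ≥ 20% of the
  collection (suppressing sequencing artefacts). Counts normalise to
  SNPs/Mbp. Against the most divergent strain as reference, substitutions
  in coding frames are split synonymous / non-synonymous (translation
  table 11).
* **HVGs**: each core gene is scored by its mean pairwise SNP count versus
  the reference; genes above `Q3 + 1.5·IQR` of that distribution are the
  highly variable genes, genes below `Q1` the conserved set.
* **Trees**: neighbour joining (Saitou–Nei) on nucleotide p-distances of
  the concatenated core (or the HVGs alone), with column-resampling
  bootstrap support.
* **Strain profiling**, with
  `RPKM = (10⁹ × reads on gene) / (total mapped reads × gene length)`:
  up to ten strain-unique marker genes per strain
  (no cross-genome hit ≥ 100 bp at ≥ 90% identity, no transposase/phage/
  integrase annotation, ≥ 500 bp from contig ends); reads count only on a
  full-length exact match on either strand; strain abundance is the mean
  marker RPKM, renormalised to proportions per time point.

A coalescent-based simulator (`simulate_pangenome()`, `simulate_reads()`)
generates genomes, truth tables and read mixtures with the same
statistical structure, so every stage is verified against planted truth.

## Worked example

```r
library(panmicrodiv)

cfg <- simulation_config(n_strains = 10, n_core_genes = 40,
                         gene_length_range = c(300, 600),
                         gain_loss_rate = 3, n_unique_genes_per_strain = 3,
                         seed = 7)
sim <- simulate_pangenome(cfg)
tab <- cluster_gene_families(sim$genomes)
part <- classify_families(tab)
part$summary
#>       class n_families
#> 1      core         40
#> 2 accessory          9
#> 3    unique         50

aln    <- build_core_alignments(tab, sim$genomes, reference = "strain01")
concat <- concat_alignments(aln)
ref    <- select_reference_strain(p_distance_matrix(concat))  # "strain09"
snps   <- do.call(rbind, lapply(aln, extract_snp_sites))
nrow(snps); nchar(concat$seqs[[1]])
#> [1] 1089
#> [1] 17873

stats <- per_gene_snp_stats(aln, ref)
detect_hvgs(stats)$hvgs        # fast-class genes exceeding Q3 + 1.5*IQR

# profile a 4-strain co-culture of the first four strains
mix <- sim$genomes[1:4]
subtab <- gene_family_table(tab$members[tab$members$genome %in% names(mix), ],
                            sort(names(mix)))
mk <- select_marker_genes(subtab, mix)
rs <- simulate_reads(mix, c(.5, .3, .15, .05), 20000, 150,
                     error_rate = 0, seed = 3)
profile_timeseries(list(t10 = rs), mk)$profile
#>   time   strain mapped_reads      rpkm proportion
#> 1  t10 strain01          520 178767.72 0.49098766
#> 2  t10 strain02          428 114449.34 0.31433647
#> 3  t10 strain03          185  50754.65 0.13939824
#> 4  t10 strain04           65  20126.49 0.05527763
```

The 1089 SNP sites over 17,873 aligned core bp are the occurrence-filtered
micro-diversity of the simulated collection; the profiling table recovers
the planted 0.5/0.3/0.15/0.05 mixture to within a few percent at 20k reads
(and within ±0.02 at 5 × 10⁵ reads).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow on a 22-strain simulated collection (simulate → pangenome →
core SNPs → HVGs/trees → co-culture profiling), writing their tables under
`results/`.

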