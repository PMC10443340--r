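---
title: "Core-genome micro-diversity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-genome micro-diversity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmicrodiv)
```

# What the package computes

`panmicrodiv` studies micro-diversity *within* a bacterial species — the
kind of variation that separates strains of *Lactobacillus crispatus*
occupying different human body sites. Starting from a collection of strain
genomes it derives, in order:

1. **Gene families (COGs).** All genes are compared all-vs-all; two genes
   are connected when a global alignment reaches 50% identity over at least
   80% of the longer sequence, and families are the connected components of
   that graph. Core families occur in every genome, unique families in
   exactly one, the remainder is accessory. Gene accumulation curves over
   random genome orderings show whether the pangenome is open.
2. **Core-genome SNPs (cgSNPs).** Each core family is aligned (the
   reference row is kept gap-free so columns map onto reference gene
   coordinates), and a column counts as a SNP site only when at least two
   bases occur and the summed occurrence of all non-majority alleles
   reaches 20% of the genomes — singleton alleles are more often assembly
   or sequencing artefacts than variants. Counts are normalised to SNPs per
   Mbp. Against the most divergent strain (the "deepest split" in the
   distance matrix, used as reference), per-genome cgSNP totals and the
   synonymous / non-synonymous split (bacterial translation table 11) are
   reported.
3. **Highly variable genes (HVGs).** Every core gene gets the mean pairwise
   SNP count of the non-reference genomes against the reference. Quartiles
   of those means are interpolated linearly from the order statistics, and
   a gene is an HVG iff its mean strictly exceeds Q3 + 1.5·IQR; genes below
   Q1 are the conserved set. HVGs typically code for surface and transport
   functions under diversifying selection, and a tree built from HVGs alone
   can group strains differently from the whole-core tree.
4. **Phylogenomics.** Nucleotide p-distances on the concatenated core
   alignment feed a classical neighbour-joining reconstruction with
   column-resampling bootstrap support.
5. **Strain deconvolution.** For each strain in a defined co-culture, up to
   ten unique marker genes are selected (no cross-genome similarity hit, no
   mobile-element annotation, not near a contig end). Metagenomic reads
   count for a marker only on a full-length exact match on either strand
   (BBMap "perfect mode" semantics); strain abundance is the mean RPKM over
   its markers, renormalised to proportions per time point.

A simulator generates strain collections and read mixtures with known truth
for every one of those stages, which is how the package tests itself.

# The simulator: what it emulates, and what it does not

`simulate_pangenome()` draws a Kingman coalescent tree over the strains
(`ape::rcoal`), rescaled to root-to-tip depth 1 so that `base_subst_rate`
reads directly as expected substitutions per site between the root and any
tip. Sequences evolve by Jukes–Cantor: per branch, the number of
substitutions per gene is Poisson(rate × length × branch length), each hit
replacing the base with one of the other three uniformly; multiple hits at
a site apply sequentially, so long branches saturate exactly as JC predicts.
There are **no indels** by default — orthologs stay positionally aligned,
which mirrors the fact that the downstream SNP analysis is site-based and
never scores indels.

Accessory structure comes from gain/loss events on branches: gains
(Poisson per branch) insert a fresh random gene inherited by the clade
below; losses act per accessory family with probability proportional to
branch length, the standard birth–death flavour, so a gained family's
survival decays smoothly with tree depth instead of collapsing whenever
the accessory pool is small. Unique genes are planted per strain, and a
fraction of unique genes
is labelled as transposase/phage/integrase so the marker blacklist has
realistic work. Genes are laid out in randomized order on one contig per
strain with random intergenic spacers; GFF3 coordinates are emitted 1-based
inclusive and round-trip exactly through `write_genome()`/`read_genome()`.

Default parameters and the reasoning behind them:

| parameter | default | why |
|---|---|---|
| `n_strains` | 22 | size of a dereplicated representative collection for a well-sampled species |
| `n_core_genes` | 500 | desk-scale stand-in for a core genome of ~1000 genes; large enough for stable quartiles |
| `gene_length_range` | 600–1500 bp | typical bacterial CDS lengths |
| `base_subst_rate` | 0.02 | gives ~2–4% pairwise core divergence, the magnitude seen between conspecific strains with hundreds of SNPs/Mbp |
| `fast_gene_fraction` | 0.05 | roughly the observed share of HVGs among core genes (~50 in ~1000) |
| `fast_rate_multiplier` | 10 | HVG per-gene SNP means run an order of magnitude above the typical gene |
| `gain_loss_rate` | 2 per branch | produces tens of accessory families on a 22-strain tree |
| `n_unique_genes_per_strain` | 12 | enough singletons that ~10 markers survive filtering, emulating the "roughly ten markers per strain" regime |
| `intergenic_spacer` | 200 bp | typical intergenic distance; also guarantees genes exist within the 500 bp contig-end exclusion zone |
| `read_length` | 150 bp | short-read shotgun metagenomics |
| `error_rate` | 0 | perfect-mode profiling discards erroneous reads anyway; error > 0 is available to measure that loss |

What the simulator does **not** model: indel mutations (a switch exists in
the alignment machinery, not the generator), recombination and horizontal
transfer with donor tracking, codon-aware substitution (rates are uniform
across positions, so the synonymous fraction of simulated SNPs is the
neutral ~25%, not the selection-shaped excess real genomes show),
paired-end structure, insert sizes, quality-dependent errors, and
compositional bias. Tests passing on simulated data therefore certify the
*bookkeeping* — clustering, filtering, counting, tree and abundance
arithmetic — not robustness to assembly artefacts or real error profiles.

# Numerical and algorithmic choices

**Clustering.** The classical pipeline (BLAST E ≤ 1e-5 then MCL) is
replaced by exact dynamic-programming alignment with the identity/coverage
criterion, and families are plain connected components. E-values depend on
database size, so the identity/coverage pair is the binding constraint;
connected components are deterministic and parameter-free, and coincide
with inflation-based clustering when families are well separated (as
simulated families are). The all-vs-all cost is contained by a shared
15-mer candidate prefilter. Exact k-mer seeding alone would be lossy for
the fast gene class — at 70% identity two sequences can share no 15-mer —
so every equal-length gene pair is additionally screened by ungapped
positional identity, which *is* the optimal alignment when divergence is
substitution-only. Within the clusterer and ANI computation the ungapped
screen also short-circuits the DP alignment whenever it already decides the
comparison; `pairwise_gene_identity()` itself always runs the full DP.
Coverage is measured against the **longer** sequence: stricter, and immune
to fragment-driven merges.

**Alignment.** Multiple alignment is unnecessary in the default indel-free
regime (members of a core family have equal length and are positionally
aligned). When lengths differ, each member is globally aligned to the
reference member and projected onto reference coordinates: reference rows
stay gap-free, insertions relative to the reference are dropped, deletions
become gaps. Column counting on such a projection is equivalent to what a
multiple aligner gives at within-species identity levels, and it keeps the
coordinate system of the reference genome.

**Occurrence filter.** "Two or more alternatives in at least 20% of the
collection" is implemented as: summed occurrence of all non-majority bases
≥ 0.20 × (number of genomes), compared with a 1e-9 slack so that a site at
exactly 20% is kept. Columns containing any gap are excluded by default
(SNP = substitution). Ties for the majority allele are broken A<C<G<T;
this affects only labelling, never the keep/drop decision.

**Quartiles.** The HVG rule needs a fixed quartile convention to be
testable; linear interpolation of order statistics (R's type 7) is used,
verified against hand-computed cases: means (1,2,3,4,100) give Q1 = 2,
Q3 = 4, cutoff 7; means (1,2,3,4) give Q1 = 1.75. The HVG inequality is
strict, so a degenerate distribution (IQR = 0, all means equal) yields no
HVGs.

**Neighbour joining.** Classical Saitou–Nei with the standard Q-criterion
and branch-length updates, implemented in-package because two behaviours
are pinned down that off-the-shelf implementations leave loose: ties in the
Q-matrix break deterministically by the lexicographic order of the joined
groups' smallest taxon labels, and negative branch lengths are clamped to
zero with the deficit shifted to the sister branch (preserving the path
length of the joined pair). On additive matrices the reconstruction is
exact to floating-point precision; tests verify both exactness and
topological agreement with an independent implementation.

**Bootstrap.** Columns of the concatenated core alignment are resampled
with replacement; each replicate rebuilds the full NJ tree; supports are
per-split frequencies × 100, attached to the internal nodes of the
full-data tree. Splits under 50% are reported — filtering is a display
decision. Supports are reproducible given the seed.

**SNPs/Mbp denominator.** The normalisation "per Mbp" can be read against
the concatenated core alignment length or against the mean genome length;
the two differ by the core fraction of the genome. Both are computed and
written (`snp_rates.tsv`); neither is privileged, and any comparison
between collections must fix one convention.

**Reporting.** Percentages are rounded half away from zero.
Reported summary percentages can disagree with re-derived ones by one unit
when a source truncated rather than rounded; the consistency checks
therefore assert agreement to one unit of the printed integer.

**Profiling.** "Perfect mode" is a full-read-length exact match on either
strand, implemented by hashing all read-length substrings of the markers
(both strands) and looking reads up against that table — identical to, and
tested against, a brute-force substring scan. Reads matching markers of
more than one strain are discarded and tallied (the pipeline warns when two
profiled strains exceed 98% ANI, where such ambiguity becomes likely); a
read matching several markers of one strain counts for each, which leaves
proportions invariant because per-strain abundance is the **mean** RPKM
over markers, not the sum. The library size in the RPKM formula is the
number of strain-assigned mapped reads of that time point. When nothing
maps at a time point, proportions are reported `NA` rather than invented.

Two small biases are accepted rather than corrected, because the published
formula is the contract: a read must fit inside a marker, so the effective
target of a marker of length L is L − read_length + 1 positions while RPKM
divides by L; and marker read counts scale with 1/(genome length), which
differs slightly between strains with different accessory content. At ten
markers of ≥600 bp per strain both effects stay well inside the ±0.05
tolerance the mixture recovery is held to.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen so the full suite
completes in minutes while every statistical check retains power: the
analysis scripts use 22 strains × 300 core genes; HVG recovery is scored on
22 strains × 500 core genes over 20 simulation replicates; NJ correctness
on 50 six-taxon simulations with ≥ 50 expected substitutions per branch;
mixture recovery on 4 strains × ~10 markers at 5 × 10⁵ error-free reads
(estimates land within ±0.05 of the planted 0.50/0.30/0.15/0.05). The
published collection the package's reference statistics describe (22
genomes, 6512 pangenome COGs, 959 core COGs) requires the original NCBI
assemblies and is deliberately not re-derived here; only its internal
arithmetic is checked.

# Known limitations

* Connected-component clustering is single-linkage: one promiscuous gene
  can bridge two families. Real mobile elements do this; the simulator's
  unique genes are random enough not to.
* The reference-projected alignment discards insertions relative to the
  reference, so variation inside such insertions is invisible — consistent
  with a reference-anchored SNP analysis, but a loss nonetheless.
* `classify_substitution()` scores each differing site against the
  reference codon mutated at that site alone; doubly-substituted codons are
  not scored along mutational paths (full Ka/Ks machinery is out of scope).
* The equal-length screen in the clusterer assumes substitution-only
  divergence; equal-length pairs whose best alignment needs compensating
  indels would be under-scored by it, though the k-mer route usually
  catches them.
* Bootstrap on concatenated data resamples sites, not genes; gene-level
  resampling would answer a different (and also interesting) question.
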