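# Gene family clustering, core/accessory/unique partition, accumulation
# curves, ANI and dereplication.

test_that("pairwise identity and coverage behave on the boundary cases", {
  set.seed(1)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(unname(pairwise_gene_identity(a, a)),
               c(1, 1))
  expect_equal(pairwise_gene_identity(strrep("A", 100),
                                      strrep("C", 100))[["identity"]], 0)
  half <- substring(a, 1, 150)
  idcov <- pairwise_gene_identity(half, a)
  expect_equal(idcov[["identity"]], 1)
  expect_equal(idcov[["coverage"]], 0.5)
  expect_error(pairwise_gene_identity("", a), "empty")
})

test_that("identical genomes cluster into one family per gene, present in all", {
  set.seed(2)
  genes <- setNames(as.list(replicate(10, paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))),
    sprintf("fam%02d", 1:10))
  genomes <- lapply(c("gA", "gB", "gC"), toy_genome, gene_seqs = genes)
  tab <- cluster_gene_families(genomes)
  expect_equal(nrow(tab$counts), 10L)
  expect_true(all(presence_matrix(tab)))
})

test_that("a gene mutated below the identity threshold becomes a singleton family", {
  set.seed(3)
  genes <- setNames(as.list(replicate(5, paste(
    sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))),
    sprintf("fam%02d", 1:5))
  gA <- toy_genome("gA", genes)
  genes_b <- genes
  # replace 60% of fam01's positions: ~40% identity, below the 50% cut
  s <- strsplit(genes_b$fam01, "")[[1]]
  idx <- sample(300, 180)
  s[idx] <- vapply(s[idx], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
  genes_b$fam01 <- paste(s, collapse = "")
  gB <- toy_genome("gB", genes_b)
  # confirm with the exact aligner that the pair fails the joint
  # identity/coverage criterion (the ends-free alignment may retreat to a
  # short high-identity window, in which case coverage fails instead)
  idcov <- pairwise_gene_identity(genes$fam01, genes_b$fam01)
  expect_false(idcov[["identity"]] >= 0.5 && idcov[["coverage"]] >= 0.8)
  tab <- cluster_gene_families(list(gA, gB))
  part <- classify_families(tab)
  expect_equal(length(part$core), 4L)
  expect_equal(length(part$unique), 2L)
})

test_that("clustering equals brute-force DP clustering and recovers simulator truth", {
  for (sd in c(7, 19)) {
    cfg <- simulation_config(n_strains = 5, n_core_genes = 8,
                             gene_length_range = c(150, 250),
                             gain_loss_rate = 1, n_unique_genes_per_strain = 1,
                             seed = sd)
    sim <- simulate_pangenome(cfg)
    tab <- cluster_gene_families(sim$genomes)
    # brute force: all-pairs exact DP alignment, no prefilter, no fast path
    gene_tab <- do.call(rbind, lapply(sim$genomes, function(g)
      data.frame(gene_id = g$genes$gene_id, seq = unname(gene_sequences(g)),
                 genome = g$strain, stringsAsFactors = FALSE)))
    gene_tab <- gene_tab[order(gene_tab$gene_id), ]
    n <- nrow(gene_tab)
    adj <- matrix(FALSE, n, n)
    cfg_clu <- clustering_config()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      idcov <- pairwise_gene_identity(gene_tab$seq[i], gene_tab$seq[j],
                                      cfg_clu)
      hit <- idcov[["identity"]] >= cfg_clu$min_identity &&
        idcov[["coverage"]] >= cfg_clu$min_coverage
      adj[i, j] <- adj[j, i] <- hit
    }
    comp <- bf_components(adj)
    bf_members <- data.frame(
      family = ave(gene_tab$gene_id, comp, FUN = min),
      gene_id = gene_tab$gene_id, stringsAsFactors = FALSE)
    expect_identical(partition_key(tab$members), partition_key(bf_members))
    # zero-rate run recovers the planted families exactly
    sim0 <- simulate_pangenome(simulation_config(
      n_strains = 6, n_core_genes = 12, gene_length_range = c(200, 400),
      base_subst_rate = 0, gain_loss_rate = 2,
      n_unique_genes_per_strain = 2, seed = sd))
    tab0 <- cluster_gene_families(sim0$genomes)
    expect_identical(partition_key(tab0$members),
                     partition_key(sim0$truth$gene_family_truth))
    expect_equal(length(classify_families(tab0)$core), 12L)
  }
  # default-condition truth recovery, including the fast gene class
  cfgd <- simulation_config(n_strains = 10, n_core_genes = 40,
                            gene_length_range = c(300, 600),
                            gain_loss_rate = 3, n_unique_genes_per_strain = 3,
                            seed = 7)
  simd <- simulate_pangenome(cfgd)
  tabd <- cluster_gene_families(simd$genomes)
  expect_identical(partition_key(tabd$members),
                   partition_key(simd$truth$gene_family_truth))
})

test_that("clustering is invariant to genome input order", {
  cfg <- simulation_config(n_strains = 5, n_core_genes = 8,
                           gene_length_range = c(200, 300),
                           n_unique_genes_per_strain = 1, seed = 13)
  sim <- simulate_pangenome(cfg)
  tab1 <- cluster_gene_families(sim$genomes)
  tab2 <- cluster_gene_families(rev(sim$genomes))
  expect_identical(tab1$members, tab2$members)
  expect_identical(tab1$counts, tab2$counts)
})

test_that("family partition is exhaustive, disjoint and matches the toy enumeration", {
  # presence patterns over 3 genomes: 111, 111, 110, 100, 010
  members <- data.frame(
    family = c("f1", "f1", "f1", "f2", "f2", "f2", "f3", "f3", "f4", "f5"),
    genome = c("g1", "g2", "g3", "g1", "g2", "g3", "g1", "g2", "g1", "g2"),
    gene_id = sprintf("gene%02d", 1:10), stringsAsFactors = FALSE)
  tab <- gene_family_table(members, c("g1", "g2", "g3"))
  part <- classify_families(tab)
  expect_setequal(part$core, c("f1", "f2"))
  expect_setequal(part$accessory, "f3")
  expect_setequal(part$unique, c("f4", "f5"))
  expect_equal(length(part$core) + length(part$accessory) +
                 length(part$unique), nrow(tab$counts))
  expect_equal(unname(part$unique_counts[c("g1", "g2", "g3")]), c(1, 1, 0))
  # accumulation: pangenome(3) = 5 and core(3) = 2 in every permutation
  acc <- accumulation_curves(tab, n_permutations = 12, seed = 4)
  last <- acc$curves[acc$curves$n_genomes == 3, ]
  expect_true(all(last$pangenome == 5))
  expect_true(all(last$core == 2))
  # monotone within every permutation
  for (p in unique(acc$curves$permutation)) {
    cur <- acc$curves[acc$curves$permutation == p, ]
    expect_true(all(diff(cur$pangenome) >= 0))
    expect_true(all(diff(cur$core) <= 0))
  }
  expect_error(accumulation_curves(tab, n_permutations = 0), "n_permutations")
})

test_that("identical genomes give flat accumulation curves equal to the core", {
  set.seed(5)
  genes <- setNames(as.list(replicate(6, paste(
    sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))),
    sprintf("fam%02d", 1:6))
  genomes <- lapply(c("gA", "gB", "gC"), toy_genome, gene_seqs = genes)
  tab <- cluster_gene_families(genomes)
  acc <- accumulation_curves(tab, n_permutations = 5, seed = 1)
  expect_true(all(acc$curves$pangenome == 6))
  expect_true(all(acc$curves$core == 6))
})

test_that("ANI matches direct site counting and is symmetric", {
  set.seed(6)
  base <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  mut <- strsplit(base, "")[[1]]
  mut[c(10, 60)] <- vapply(mut[c(10, 60)], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
  gA <- toy_genome("gA", list(fam01 = base))
  gB <- toy_genome("gB", list(fam01 = paste(mut, collapse = "")))
  tab <- toy_family_table(list(gA, gB))
  expect_equal(compute_ani(gA, gB, tab), 98)
  expect_equal(compute_ani(gA, gA, toy_family_table(list(gA))), 100)
  # simulator pair: ANI within 0.1 of 100 * (1 - observed p), brute counted
  cfg <- simulation_config(n_strains = 2, n_core_genes = 15,
                           gene_length_range = c(300, 500),
                           gain_loss_rate = 0, n_unique_genes_per_strain = 0,
                           seed = 30)
  sim <- simulate_pangenome(cfg)
  tab2 <- cluster_gene_families(sim$genomes)
  ani <- compute_ani(sim$genomes[[1]], sim$genomes[[2]], tab2)
  expect_equal(ani, compute_ani(sim$genomes[[2]], sim$genomes[[1]], tab2),
               tolerance = 1e-9)
  s1 <- gene_sequences(sim$genomes[[1]]); s2 <- gene_sequences(sim$genomes[[2]])
  fams <- sim$genomes[[1]]$genes$family
  p_per_fam <- vapply(fams, function(fam) {
    a <- charToRaw(s1[[paste0("strain01_", fam)]])
    b <- charToRaw(s2[[paste0("strain02_", fam)]])
    mean(a != b)
  }, numeric(1))
  expect_lt(abs(ani - 100 * (1 - mean(p_per_fam))), 0.1)
})

test_that("dereplication collapses single-linkage chains and keeps distinct genomes", {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    paste(v, collapse = "")
  }
  sB <- mutate_at(base, 1:5)        # A~B 99.5
  sC <- mutate_at(sB, 101:105)      # B~C 99.5, A~C 99.0
  gA <- toy_genome("gA", list(fam01 = base))
  gB <- toy_genome("gB", list(fam01 = sB))
  gC <- toy_genome("gC", list(fam01 = sC))
  tab <- toy_family_table(list(gA, gB, gC))
  der <- dereplicate(list(gA, gB, gC), dereplication_config(99), tab)
  expect_equal(length(der$representatives), 1L)
  expect_equal(length(unique(der$clusters$cluster)), 1L)
  # identical pair + one divergent genome -> two representatives
  gD <- toy_genome("gD", list(fam01 = base))
  tab2 <- toy_family_table(list(gA, gD, gC))
  der2 <- dereplicate(list(gA, gD, gC), dereplication_config(99), tab2)
  expect_equal(length(der2$representatives), 2L)
  # all pairs at or below the threshold -> everything retained
  der3 <- dereplicate(list(gA, gC), dereplication_config(99.6),
                      toy_family_table(list(gA, gC)))
  expect_equal(length(der3$representatives), 2L)
})
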