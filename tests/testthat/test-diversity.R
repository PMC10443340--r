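# Per-gene variability, HVG detection, p-distances, neighbour joining,
# bootstrap support and reference strain selection.

test_that("per-gene stats average the non-reference rows against the reference", {
  ref <- strrep("ACGT", 10)
  two <- ref; substring(two, 1, 1) <- "G"; substring(two, 6, 6) <- "T"
  four <- ref
  for (p in c(3, 7, 11, 15)) substring(four, p, p) <- "C"
  aln <- core_alignment("toy", c(gR = ref, gA = two, gB = four))
  st <- per_gene_snp_stats(list(aln), reference = "gR")
  expect_equal(st$mean_snps, 3)
  expect_equal(st$n_comparisons, 2L)
  st_all <- per_gene_snp_stats(list(aln), reference = "gR", all_pairs = TRUE)
  expect_equal(st_all$n_comparisons, 3L)
})

test_that("HVG detection reproduces the interpolated-quartile worked examples", {
  st <- data.frame(family = sprintf("f%d", 1:5),
                   mean_snps = c(1, 2, 3, 4, 100))
  hv <- detect_hvgs(st)
  expect_equal(hv$q1, 2); expect_equal(hv$q3, 4)
  expect_equal(hv$cutoff, 7)
  expect_equal(hv$hvgs, "f5")
  # degenerate distribution: no mean strictly exceeds Q3 -> no HVGs
  flat <- data.frame(family = sprintf("f%d", 1:6), mean_snps = rep(5, 6))
  expect_length(detect_hvgs(flat)$hvgs, 0L)
  expect_length(conserved_genes(flat), 0L)
  # conserved set below the interpolated Q1 = 1.75
  st4 <- data.frame(family = sprintf("f%d", 1:4), mean_snps = c(1, 2, 3, 4))
  expect_equal(conserved_genes(st4), "f1")
  expect_error(detect_hvgs(st4[1:3, ]), ">= 4")
})

test_that("HVG sets are invariant to family input order and zero-rate genes are conserved", {
  set.seed(41)
  st <- data.frame(family = sprintf("f%02d", 1:40),
                   mean_snps = c(rgamma(36, 4, 1), 60, 75, 80, 90))
  hv1 <- detect_hvgs(st)
  hv2 <- detect_hvgs(st[sample(nrow(st)), ])
  expect_identical(hv1$hvgs, hv2$hvgs)
  expect_identical(hv1$cutoff, hv2$cutoff)
  # planted zero-rate genes among mutated genes are all selected as conserved
  st0 <- data.frame(family = sprintf("f%02d", 1:20),
                    mean_snps = c(rep(0, 5), rgamma(15, 20, 1)))
  expect_true(all(sprintf("f%02d", 1:5) %in% conserved_genes(st0)))
})

test_that("p-distances equal the brute-force column scan", {
  ident <- core_alignment("i", setNames(rep(strrep("ACGT", 25), 3),
                                        c("a", "b", "c")))
  expect_true(all(p_distance_matrix(ident) == 0))
  set.seed(51)
  seqs <- random_alignment(10, 500, 0.08)
  D <- p_distance_matrix(core_alignment("r", seqs))
  expect_equal(D, t(D), tolerance = 1e-12)
  rows <- strsplit(seqs, "")
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(D[i, j], mean(rows[[i]] != rows[[j]]))
  }
  # two rows differing at 5 of 100 columns
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 5), strrep("A", 95))
  D2 <- p_distance_matrix(core_alignment("t", c(x = a, y = b, z = a)))
  expect_equal(D2["x", "y"], 0.05)
})

test_that("neighbour joining solves the 3-taxon and 4-taxon closed forms", {
  D3 <- matrix(c(0, 5, 6, 5, 0, 7, 6, 7, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$tip.label), c("A", "B", "C"))
  co <- ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(co, D3, tolerance = 1e-12)
  # additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:4))
  true_t <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D4 <- ape::cophenetic.phylo(true_t)
  t4 <- neighbor_joining(D4[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  expect_equal(ape::dist.topo(ape::unroot(true_t), t4), 0,
               ignore_attr = TRUE)
  co4 <- ape::cophenetic.phylo(t4)[rownames(D4), rownames(D4)]
  expect_equal(co4, D4, tolerance = 1e-9)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbour joining recovers random additive trees and agrees with ape", {
  set.seed(61)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(D))
    D <- D[ord, ord]
    mine <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), mine), 0,
                 ignore_attr = TRUE)
    theirs <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, theirs), 0, ignore_attr = TRUE)
  }
})

test_that("reference strain selection picks the most divergent genome", {
  D <- matrix(0.01, 4, 4,
              dimnames = list(c("g1", "g2", "g3", "gZ"),
                              c("g1", "g2", "g3", "gZ")))
  diag(D) <- 0
  D["gZ", c("g1", "g2", "g3")] <- D[c("g1", "g2", "g3"), "gZ"] <- 0.1
  expect_equal(select_reference_strain(D), "gZ")
  Deq <- matrix(0.05, 3, 3, dimnames = list(c("b", "a", "c"),
                                            c("b", "a", "c")))
  diag(Deq) <- 0
  expect_equal(select_reference_strain(Deq), "a")
  # simulated long terminal branch is selected in nearly every replicate
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd)
    tr <- ape::rcoal(6)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tip_edges <- which(tr$edge[, 2] <= 6)
    long <- sample(tip_edges, 1)
    tr$edge.length[long] <- tr$edge.length[long] + 2
    seqs <- evolve_alignment(tr, 2000, 0.05)
    D <- p_distance_matrix(core_alignment("sim", seqs))
    if (select_reference_strain(D) == tr$tip.label[tr$edge[long, 2]]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("bootstrap support is deterministic, binary for one replicate, and maximal for a clean split", {
  # alignment whose every variant column separates {a,b,c} from {d,e,f}
  block1 <- strrep("A", 40); block2 <- strrep("C", 40)
  neutral <- strrep("G", 200)
  seqs <- c(a = paste0(block1, neutral), b = paste0(block1, neutral),
            c = paste0(block1, neutral), d = paste0(block2, neutral),
            e = paste0(block2, neutral), f = paste0(block2, neutral))
  # small asymmetric noise so NJ has non-zero within-group branches
  substring(seqs[["a"]], 241, 241) <- "T"
  substring(seqs[["d"]], 241, 241) <- "T"
  aln <- core_alignment("sig", seqs)
  bt <- bootstrap_support(aln, n_replicates = 30, seed = 9)
  sup <- attr(bt, "support")
  key_abc <- paste(sort(c("d", "e", "f")), collapse = "\r")
  expect_equal(sup$support[sup$split == key_abc], 100)
  bt2 <- bootstrap_support(aln, n_replicates = 30, seed = 9)
  expect_identical(attr(bt2, "support"), sup)
  bt1 <- bootstrap_support(aln, n_replicates = 1, seed = 4)
  s1 <- attr(bt1, "support")$support
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("the HVG tree follows the fast-gene signal when it conflicts with the core signal", {
  taxa <- c("t1", "t2", "t3", "t4", "t5", "t6")
  mk_gene <- function(split_tips, n_var, n_const, label_base = "A",
                      label_alt = "C") {
    vapply(taxa, function(tx) {
      ch <- if (tx %in% split_tips) label_base else label_alt
      paste0(strrep(ch, n_var), strrep("G", n_const))
    }, character(1))
  }
  # ten slow genes support t1,t2,t3 | t4,t5,t6 with 10 variant columns each
  slow <- lapply(1:10, function(i)
    core_alignment(sprintf("slow%02d", i),
                   mk_gene(c("t1", "t2", "t3"), 10, 90)))
  # two fast genes support t1,t4,t5 | t2,t3,t6 with 40 variant columns each
  fast <- lapply(1:2, function(i)
    core_alignment(sprintf("fast%02d", i),
                   mk_gene(c("t1", "t4", "t5"), 40, 60)))
  alns <- c(slow, fast)
  names(alns) <- vapply(alns, `[[`, character(1), "family")
  st <- per_gene_snp_stats(alns, reference = "t1")
  hv <- detect_hvgs(st)
  expect_setequal(hv$hvgs, c("fast01", "fast02"))
  full_tree <- neighbor_joining(p_distance_matrix(concat_alignments(alns)))
  ht <- hvg_tree(alns, hv$hvgs)
  expect_true(tree_has_split(full_tree, c("t1", "t2", "t3")))
  expect_true(tree_has_split(ht, c("t1", "t4", "t5")))
  expect_false(tree_has_split(ht, c("t1", "t2", "t3")))
  # HVG set = all families reproduces the full-core tree
  ht_all <- hvg_tree(alns, names(alns))
  expect_equal(ape::dist.topo(ht_all, full_tree), 0, ignore_attr = TRUE)
  expect_error(hvg_tree(alns, character(0)), "empty")
})
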