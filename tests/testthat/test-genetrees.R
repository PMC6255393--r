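test_that("hamming distances count genotype-code mismatches over joint calls", {
  g <- cbind(a = c(0L, 1L, 2L, 1L), b = c(0L, 2L, 2L, 1L), c = c(2L, 2L, 0L, 0L))
  h <- hamming_distances(make_tab(g))
  expect_equal(h$d["a", "b"], 0.25)  # codes (0,1,2,1) vs (0,2,2,1)
  expect_equal(h$d["a", "a"], 0)
  expect_true(isSymmetric(h$d))
  # saturation: all-0 vs all-2
  g2 <- cbind(a = rep(0L, 5), b = rep(2L, 5), c = rep(1L, 5))
  expect_equal(hamming_distances(make_tab(g2))$d["a", "b"], 1)
  # missing data reduce the pair's site count
  g3 <- cbind(a = c(0L, NA, 1L), b = c(0L, 1L, 2L), c = c(1L, 1L, 1L))
  expect_equal(hamming_distances(make_tab(g3))$n["a", "b"], 2L)
})

test_that("three taxa give the unique topology with three-point branch lengths", {
  d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(length(tr$tip.label), 3L)
  cp <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, d)
})

test_that("NJ reconstructs additive matrices exactly (topology and lengths)", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    d0 <- ape::cophenetic.phylo(ape::unroot(tr0))
    d0 <- d0[sort(rownames(d0)), sort(rownames(d0))]
    tr <- neighbor_joining(d0)
    expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(d0), colnames(d0)] - d0)),
                 0, tolerance = 1e-8)
  }
})

test_that("NJ agrees with the ape reference implementation on additive matrices", {
  set.seed(13)
  for (i in 1:10) {
    tr0 <- ape::rtree(8, br = function(k) runif(k, 0.1, 1))
    d0 <- ape::cophenetic.phylo(ape::unroot(tr0))
    mine <- neighbor_joining(d0)
    ref <- ape::nj(d0)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equidistant taxa give a deterministic zero-length resolution", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # internal branch has zero length
  nt <- length(t1$tip.label)
  internal <- t1$edge[, 2] > nt
  expect_true(all(abs(t1$edge.length[internal]) < 1e-12))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("window trees respect the minimum-variant rule and tiling arithmetic", {
  set.seed(14)
  # 250 kb chromosome: dense first two windows, sparse tail
  pos <- sort(c(sample(1:100000, 150), sample(100001:200000, 120),
                sample(200001:250000, 99)))
  g <- matrix(sample(0:2, length(pos) * 4, TRUE), length(pos), 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  tab <- make_tab(g, pos = pos)
  ws <- window_trees(tab, window_bp = 100000L, min_variants = 100L,
                     chrom_lengths = c(chr1 = 250000L))
  expect_equal(nrow(ws$windows), 3L)
  expect_equal(ws$windows$status, c("retained", "retained", "skipped"))
  expect_equal(ws$windows$reason[3], "too_few_variants")
  expect_equal(length(ws$trees), 2L)
  # 99 variants is under the default minimum
  ws99 <- window_trees(subset_sites(tab, tab$sites$pos > 200000),
                       window_bp = 100000L, min_variants = 100L)
  expect_equal(sum(ws99$windows$status == "retained"), 0L)
})

test_that("window trees recover planted topologies in mutation-rich windows", {
  fx <- radsim_fixture()
  ws <- window_trees(fx$tab, window_bp = 100000L, min_variants = 100L)
  trio <- fx$cfg$trio
  truth <- fx$sim$truth$windows
  idx <- as.integer(names(ws$trees))
  ok <- 0; tot <- 0
  for (i in seq_along(ws$trees)) {
    w <- ws$windows[idx[i], ]
    tw <- truth[truth$chrom == w$chrom & truth$start == w$start, ]
    if (tw$trio_mutations < 60) next  # genealogy left too little signal
    pairm <- sort(switch(tw$trio_pair, trio[2:3], trio[c(1, 3)], trio[1:2]))
    rt <- ape::root(ws$trees[[i]], outgroup = "out", resolve.root = TRUE)
    hit <- any(vapply(radpop:::clade_sets(rt),
                      function(s) length(s) == 2 && all(s == pairm), logical(1)))
    tot <- tot + 1; ok <- ok + hit
  }
  expect_gt(tot, 10)
  expect_gte(ok / tot, 0.95)
})

test_that("subtree stage-1 arithmetic matches a chi-square oracle and stage-2 flags the chromosome", {
  set.seed(15)
  # one clade at 80% on chromosome A, 20% elsewhere; a null clade at 50%
  chrom <- rep(c("A", "B", "C"), each = 200)
  enriched <- rbinom(600, 1, ifelse(chrom == "A", 0.8, 0.2)) == 1
  nullcl <- rbinom(600, 1, 0.5) == 1
  presence <- rbind(enriched = enriched, nullcl = nullcl)
  res <- subtree_prevalence_test(presence, chrom)
  # oracle: prop.test equals chisq.test on the 2 x k contingency table
  tab2 <- rbind(tapply(enriched, chrom, sum), tapply(!enriched, chrom, sum))
  oracle <- suppressWarnings(chisq.test(tab2, correct = FALSE))
  i <- which(res$stage1$clade == "enriched")
  expect_equal(res$stage1$chisq[i], unname(oracle$statistic))
  expect_equal(res$stage1$p[i], oracle$p.value)
  expect_equal(res$stage1$p_bonferroni, pmin(1, res$stage1$p * 2))
  expect_lt(res$stage1$p_bonferroni[i], 0.05)
  s2a <- res$stage2[res$stage2$clade == "enriched" & res$stage2$chrom == "A", ]
  expect_lt(s2a$p_bonferroni, 0.05)
  # stage-2 Bonferroni n = significant clades x chromosomes
  n_sig <- sum(res$stage1$p_bonferroni < 0.05)
  expect_equal(nrow(res$stage2), n_sig * 3L)
})

test_that("a clade present in every window is never significant", {
  presence <- rbind(always = rep(TRUE, 90))
  res <- subtree_prevalence_test(presence, rep(c("A", "B", "C"), each = 30))
  expect_equal(res$stage1$p[1], 1)
})

test_that("clade catalogs from window trees exclude trivial clades", {
  fx <- radsim_fixture()
  ws <- window_trees(fx$tab, window_bp = 100000L, min_variants = 100L)
  st <- subtree_tests(ws, root_taxon = "out")
  sizes <- lengths(strsplit(st$catalog$clades, "|", fixed = TRUE))
  expect_true(all(sizes >= 2))
  expect_true(all(sizes < nrow(fx$tab$samples)))
  expect_true(all(rowSums(st$catalog$presence) >= 1))
})
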