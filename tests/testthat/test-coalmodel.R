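mat_pow_test <- function(P, k) {   # plain repeated multiplication oracle
  R <- diag(nrow(P)); dimnames(R) <- dimnames(P)
  for (i in seq_len(k)) R <- R %*% P
  R
}

test_that("gene-flow modes expand m correctly and validate inputs", {
  expect_equal(gene_flow_model(1000, m = 1e-4, mode = "symmetric")$m2, 1e-4)
  expect_equal(gene_flow_model(1000, m = 1e-4, mode = "unidirectional")$m2, 0)
  m <- gene_flow_model(1000, m = 1e-4, mode = "asymmetric")
  expect_equal(m$m1, 2 * m$m2)
  expect_error(gene_flow_model(1, m = 0), "N must be")
  expect_error(gene_flow_model(1000, m = 0, t1 = 2, t2 = 1), "t2 > t1")
})

test_that("phase-1 transitions are row-stochastic and match hand expansion", {
  for (i in 1:5) {
    set.seed(i)
    mod <- gene_flow_model(N = sample(100:10000, 1), m1 = runif(1, 0, 0.1),
                           m2 = runif(1, 0, 0.1))
    P <- build_phase1_chain(mod)$P
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(P >= 0))
    # hand expansion from (a@A, c@C): both migrate/stay independently, then
    # co-located lineages coalesce with probability 1/N
    m1 <- mod$m1; m2 <- mod$m2; N <- mod$N
    expect_equal(P["aA.cC", "aC.cC"], m1 * (1 - m2) * (1 - 1 / N))
    expect_equal(P["aA.cC", "aA.cA"], (1 - m1) * m2 * (1 - 1 / N))
    expect_equal(P["aA.cC", "aA.cC"], (1 - m1) * (1 - m2))
    expect_equal(P["aA.cC", "coal"],
                 (m1 * (1 - m2) + (1 - m1) * m2) / N)
  }
})

test_that("without migration the phase-1 chain never coalesces", {
  P <- build_phase1_chain(gene_flow_model(1000, m = 0))$P
  expect_equal(P["aA.cC", "aA.cC"], 1)
  expect_equal(P["aA.cC", "coal"], 0)
})

test_that("phase-2 reachability reflects lineage locations", {
  mod <- gene_flow_model(1000, m = 0)
  c2 <- build_phase2_chain(mod, phase1_end = c(1, 0, 0, 0, 0))
  # mass in (a@A, c@C) can only reach (b,c) coalescence before t2
  P <- c2$P
  k <- mat_pow_test(P, 5000)
  v <- c2$start %*% k
  expect_gt(v[1, "T1"], 0)
  expect_equal(unname(v[1, "T2"]), 0)
  expect_equal(unname(v[1, "T3"]), 0)
  # mass in (a@C, c@A) reaches (a,b): the introgression-driven path
  c2b <- build_phase2_chain(mod, phase1_end = c(0, 0, 0, 1, 0))
  vb <- c2b$start %*% k
  expect_gt(vb[1, "T3"], 0)
  expect_equal(unname(vb[1, "T2"]), 0)
  # phase-1 coalesced mass enters absorbed T2
  c2c <- build_phase2_chain(mod, phase1_end = c(0, 0, 0, 0, 1))
  expect_equal(unname(c2c$start["T2"]), 1)
  expect_error(build_phase2_chain(mod, phase1_end = c(0.5, 0, 0, 0, 0)),
               "not a probability distribution")
})

test_that("matrix powers by squaring equal iterated multiplication", {
  mod <- gene_flow_model(500, m = 0.01)
  P <- build_phase1_chain(mod)$P
  expect_lt(max(abs(radpop:::mat_pow(P, 137) - mat_pow_test(P, 137))), 1e-12)
})

test_that("no-migration topology distribution matches the closed form", {
  N <- 10000
  td <- topology_distribution(gene_flow_model(N, m = 0, t1 = 1, t2 = 2, tail = 1))
  q <- (1 - 1 / N)^N; r <- (1 - 3 / N)^N
  expect_equal(td$pT1, (1 - q) + q * (1 - r) / 3, tolerance = 1e-9)
  expect_equal(td$pT2, q * (1 - r) / 3, tolerance = 1e-9)
  expect_equal(td$pT3, q * (1 - r) / 3, tolerance = 1e-9)
  expect_equal(td$pNone, q * r, tolerance = 1e-9)
  # large-N limits quoted to four decimals (O(1/N) approximations)
  expect_lt(abs(td$pT1 - 0.7486), 2e-4)
  expect_lt(abs(td$pNone - 0.0183), 2e-4)
})

test_that("probabilities always sum to one and stay in range", {
  set.seed(17)
  for (i in 1:5) {
    mod <- gene_flow_model(N = sample(500:5000, 1), m = runif(1, 0, 5e-4),
                           mode = sample(c("symmetric", "unidirectional",
                                           "asymmetric"), 1))
    td <- topology_distribution(mod)
    v <- c(td$pT1, td$pT2, td$pT3, td$pNone)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("gene flow between a and c inflates T2 over T3", {
  td <- topology_distribution(gene_flow_model(N = 11667, m = 2e-5))
  expect_gt(td$pT2, td$pT3)
  expect_gt(td$pT2, td$pNone)
})

test_that("chain propagation matches the event-level Monte-Carlo simulator", {
  for (mode in c("symmetric", "unidirectional", "asymmetric")) {
    mod <- gene_flow_model(N = 1000, m = 2e-4, mode = mode)
    td <- topology_distribution(mod)
    s <- simulate_genealogies(mod, n_loci = 20000, theta = 1, seed = 2024)
    p <- c(td$pT1, td$pT2, td$pT3, td$pNone)
    phat <- unname(s$proportions)
    se <- sqrt(p * (1 - p) / s$n_loci)
    expect_true(all(abs(phat - p) <= 3 * se + 1e-12),
                info = paste(mode, paste(round(phat - p, 5), collapse = " ")))
  }
})

test_that("swapping migration direction swaps T2 and T3 asymmetry", {
  # unidirectional A->C flow versus the reverse: relabeling A and C swaps
  # which discordant topology is inflated
  fwd <- topology_distribution(gene_flow_model(N = 2000, m1 = 2e-4, m2 = 0))
  rev <- topology_distribution(gene_flow_model(N = 2000, m1 = 0, m2 = 2e-4))
  expect_gt(fwd$pT2, fwd$pT3)
  expect_gt(rev$pT2, rev$pT3)  # both directions inflate a-c coalescence
})

test_that("a longer tail horizon monotonically shrinks pNone", {
  pn <- vapply(c(0.5, 1, 2, 4), function(tl)
    topology_distribution(gene_flow_model(2000, m = 1e-4, tail = tl))$pNone,
    numeric(1))
  expect_true(all(diff(pn) < 0))
})

test_that("simulated D is null without migration and positive with it", {
  s0 <- simulate_genealogies(gene_flow_model(2000, m = 0), 4000, theta = 30,
                             seed = 31)
  expect_lt(abs(s0$D), 0.1)
  s1 <- simulate_genealogies(gene_flow_model(2000, m = 0.25 / 2000), 4000,
                             theta = 30, seed = 32)
  expect_gt(s1$D, 0.3)
})

test_that("grid fitting recovers self-consistent and analytic optima", {
  m_grid <- c(0, 5e-5, 2e-4); N_grid <- c(1000, 2000)
  target <- topology_distribution(gene_flow_model(2000, m = 5e-5))
  obs <- c(target$pT1, target$pT2, target$pT3) / (1 - target$pNone)
  fit <- fit_grid(obs, m_grid, N_grid)
  expect_equal(fit$best$m, 5e-5)
  expect_equal(fit$best$N, 2000)
  expect_equal(fit$best$distance, 0, tolerance = 1e-18)
  # the no-migration closed form is fitted by m = 0
  N <- 1000; q <- (1 - 1 / N)^N; r <- (1 - 3 / N)^N
  obs0 <- c((1 - q) + q * (1 - r) / 3, q * (1 - r) / 3, q * (1 - r) / 3)
  obs0 <- obs0 / sum(obs0)
  fit0 <- fit_grid(obs0, m_grid, N_grid)
  expect_equal(fit0$best$m, 0)
  expect_error(fit_grid(obs, numeric(0), N_grid), "empty grid")
})

test_that("doubling N at fixed m raises gene-tree discordance", {
  disc <- vapply(c(1000, 2000, 4000), function(N) {
    td <- topology_distribution(gene_flow_model(N, m = 5e-5))
    (td$pT2 + td$pT3) / (1 - td$pNone)
  }, numeric(1))
  expect_true(all(diff(disc) > 0))
})
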