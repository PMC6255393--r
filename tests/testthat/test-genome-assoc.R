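test_that("an exactly linear response is fitted to machine precision", {
  b <- data.frame(x = seq(1, 10, length.out = 40),
                  is_chr4 = rep(c(TRUE, FALSE), 20))
  b$y <- 2 + 3 * b$x
  fit <- chr4_regression(b, "y", "x")
  expect_equal(unname(coef(fit$pooled)), c(2, 3), tolerance = 1e-10)
  expect_equal(summary(fit$pooled)$r.squared, 1, tolerance = 1e-10)
  expect_false(fit$chr4_significant)
})

test_that("log flags recover a power-law exponent on the transformed scale", {
  set.seed(21)
  b <- data.frame(x = runif(60, 1, 50), is_chr4 = FALSE)
  b$y <- 4 * b$x^1.7
  fit <- chr4_regression(b, "y", "x", log_y = TRUE, log_x = TRUE)
  expect_equal(unname(coef(fit$pooled)[2]), 1.7, tolerance = 1e-10)
  expect_equal(unname(coef(fit$pooled)[1]), log10(4), tolerance = 1e-10)
})

test_that("a planted chromosome-four offset is detected with high power", {
  set.seed(22)
  hits <- 0; n_rep <- 60
  for (i in seq_len(n_rep)) {
    b <- data.frame(x = runif(210, 0, 5),
                    is_chr4 = rep(c(rep(FALSE, 6), TRUE), 30))
    b$y <- 1 - 0.2 * b$x + 0.3 * b$is_chr4 + rnorm(210, 0, 0.15)
    fit <- chr4_regression(b, "y", "x")
    hits <- hits + fit$chr4_significant
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("randomly permuted chromosome labels are flagged at no more than the alpha rate", {
  set.seed(23)
  hits <- 0; n_rep <- 100
  for (i in seq_len(n_rep)) {
    b <- data.frame(x = runif(120, 0, 5))
    b$y <- 1 + 0.5 * b$x + rnorm(120, 0, 0.2)
    b$is_chr4 <- sample(rep(c(TRUE, FALSE), c(17, 103)))
    fit <- chr4_regression(b, "y", "x")
    hits <- hits + fit$chr4_significant
  }
  # two chances to trigger (offset or interaction) at alpha = 0.05 each
  expect_lte(hits / n_rep, 0.10 + 3 * sqrt(0.1 * 0.9 / n_rep))
})

test_that("degenerate regressions are flagged rather than fitted", {
  b <- data.frame(x = 1:10, y = 5, is_chr4 = FALSE)
  expect_true(chr4_regression(b, "y", "x")$degenerate)
  b2 <- data.frame(x = rep(1, 10), y = rnorm(10), is_chr4 = FALSE)
  expect_error(chr4_regression(b2, "y", "x"), "distinct x")
})

test_that("partial Kendall tau matches brute-force pair counting", {
  tau_b <- function(u, v) {
    n <- length(u); C <- 0; D <- 0; tu <- 0; tv <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      su <- sign(u[j] - u[i]); sv <- sign(v[j] - v[i])
      if (su == 0 && sv == 0) { tu <- tu + 1; tv <- tv + 1 }
      else if (su == 0) tu <- tu + 1
      else if (sv == 0) tv <- tv + 1
      else if (su == sv) C <- C + 1 else D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    (C - D) / sqrt((n0 - tu) * (n0 - tv))
  }
  set.seed(24)
  for (i in 1:5) {
    x <- sample(1:4, 6, TRUE); y <- sample(1:4, 6, TRUE); z <- rnorm(6)
    txy <- tau_b(x, y); txz <- tau_b(x, z); tyz <- tau_b(y, z)
    want <- (txy - txz * tyz) / sqrt((1 - txz^2) * (1 - tyz^2))
    expect_equal(kendall_partial(x, y, z)$tau, want, tolerance = 1e-12)
  }
})

test_that("partial tau is symmetric, transform-invariant, and 1 for identical vectors", {
  set.seed(25)
  x <- rnorm(30); y <- x + rnorm(30); z <- rnorm(30)
  expect_equal(kendall_partial(x, y, z)$tau, kendall_partial(y, x, z)$tau)
  expect_equal(kendall_partial(exp(x), y^3 + y, z)$tau,
               kendall_partial(x, y, z)$tau, tolerance = 1e-12)
  expect_equal(kendall_partial(x, x, z)$tau, 1, tolerance = 1e-12)
  # conditioning on an independent z barely moves tau
  expect_equal(kendall_partial(x, y, z)$tau, cor(x, y, method = "kendall"),
               tolerance = 0.1)
  expect_true(kendall_partial(x, y, x)$undefined)
})

test_that("Fisher enrichment equals hypergeometric enumeration on small tables", {
  hyper_p <- function(a, b, c, d) {
    # two-sided: sum of probabilities of tables as or less likely
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(26)
  for (i in 1:25) {
    cnt <- sample(0:15, 4, TRUE)
    tab <- data.frame(term = "t", in_group = cnt[1], out_group = cnt[2],
                      in_background = cnt[3], out_background = cnt[4])
    got <- fisher_enrichment(tab, n_terms = 1)
    expect_equal(got$p, hyper_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9, info = paste(cnt, collapse = ","))
  }
})

test_that("proportional tables are null and Bonferroni caps at one", {
  tab <- data.frame(term = c("null", "enr"),
                    in_group = c(10L, 12L), out_group = c(90L, 88L),
                    in_background = c(100L, 10L), out_background = c(900L, 890L))
  got <- fisher_enrichment(tab, n_terms = 1936L)
  expect_equal(got$p[1], 1)
  expect_equal(got$p_bonferroni, pmin(1, got$p * 1936))
  expect_equal(fisher_enrichment(transform(tab, in_group = c(10L, 12L)),
                                 n_terms = 1936L)$p_bonferroni[1], 1)
  expect_error(fisher_enrichment(transform(tab, in_group = -1L)), "negative")
})

test_that("repeat permutation p-values are extreme, smoothed and reproducible", {
  lens <- c(chr1 = 8e6, chr4 = 2e6)
  r1 <- repeat_permutation(100, 100, lens, "chr4", n_sims = 1000, seed = 9)
  expect_equal(r1$p, 1 / 1001)   # all insertions on a 20% chromosome
  r2 <- repeat_permutation(100, 100, lens, "chr4", n_sims = 1000, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_error(repeat_permutation(100, 5, lens, "chrX"), "absent")
  expect_error(repeat_permutation(0, 0, lens, "chr4"), ">= 1 insertion")
})

test_that("repeat permutation does not over-reject under the uniform null", {
  # p-values are discrete and (with add-one smoothing) conservative, so
  # calibration is checked as type-I coverage at several thresholds
  set.seed(27)
  lens <- c(chr1 = 5e6, chr2 = 3e6, chr4 = 2e6)
  ps <- replicate(200, {
    obs <- rbinom(1, 60, 0.2)
    repeat_permutation(60, obs, lens, "chr4", n_sims = 300,
                       seed = sample.int(1e6, 1))$p
  })
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_lte(mean(ps <= 0.20), 0.25)
  expect_gt(mean(ps), 0.45)
})
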