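#' Regression with a chromosome-four contrast
#'
#' Fits (1) `y ~ x` pooled over all bins and (2) `y ~ x + is_chr4`, adding an
#' `x:is_chr4` interaction when that term is significant at `alpha`. When the
#' chromosome term is significant, separate models for the focal chromosome
#' and the rest of the genome are also fitted. Ordinary least squares on
#' optionally log-transformed variables.
#'
#' @param bins data.frame with the response, predictor and `is_chr4` columns
#' @param y,x column names of response and predictor
#' @param log_y,log_x log10-transform the variable before fitting
#' @param alpha significance level for the interaction/contrast decisions
#' @return list: pooled, contrast (lm fits), interaction_included,
#'   chr4_significant, chr4_fit, rest_fit, coefficients table
#' @export
chr4_regression <- function(bins, y, x, log_y = FALSE, log_x = FALSE,
                            alpha = 0.05) {
  d <- data.frame(y = bins[[y]], x = bins[[x]], is_chr4 = as.logical(bins$is_chr4))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (log_y) d$y <- log10(d$y)
  if (log_x) d$x <- log10(d$x)
  d <- d[is.finite(d$y) & is.finite(d$x), , drop = FALSE]
  if (length(unique(d$x)) < 3) stop("need >= 3 distinct x values")
  if (length(unique(d$y)) == 1)
    return(list(degenerate = TRUE, reason = "constant response"))
  pooled <- stats::lm(y ~ x, data = d)
  with_int <- stats::lm(y ~ x * is_chr4, data = d)
  cf <- summary(with_int)$coefficients
  int_p <- if ("x:is_chr4TRUE" %in% rownames(cf)) cf["x:is_chr4TRUE", 4] else NA
  interaction_included <- !is.na(int_p) && int_p < alpha
  contrast <- if (interaction_included) with_int else
    stats::lm(y ~ x + is_chr4, data = d)
  ccf <- summary(contrast)$coefficients
  chr4_p <- if ("is_chr4TRUE" %in% rownames(ccf)) ccf["is_chr4TRUE", 4] else NA
  chr4_significant <- (!is.na(chr4_p) && chr4_p < alpha) || interaction_included
  chr4_fit <- rest_fit <- NULL
  if (chr4_significant && sum(d$is_chr4) >= 3 && sum(!d$is_chr4) >= 3) {
    chr4_fit <- stats::lm(y ~ x, data = d[d$is_chr4, ])
    rest_fit <- stats::lm(y ~ x, data = d[!d$is_chr4, ])
  }
  list(degenerate = FALSE, pooled = pooled, contrast = contrast,
       interaction_included = interaction_included,
       interaction_p = int_p, chr4_p = chr4_p,
       chr4_significant = chr4_significant,
       chr4_fit = chr4_fit, rest_fit = rest_fit,
       adj_r_squared = summary(contrast)$adj.r.squared)
}

#' Partial Kendall correlation
#'
#' `tau_xy.z = (tau_xy - tau_xz tau_yz) / sqrt((1 - tau_xz^2)(1 - tau_yz^2))`
#' with Kendall tau-b components; significance by the normal approximation
#' for tau, `var = 2(2n + 5) / (9 n (n - 1))`.
#'
#' @param x,y,z equal-length numeric vectors (n >= 3)
#' @return list(tau, tau_xy, tau_xz, tau_yz, z_score, p, undefined)
#' @export
kendall_partial <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 3)
  txy <- stats::cor(x, y, method = "kendall")
  txz <- stats::cor(x, z, method = "kendall")
  tyz <- stats::cor(y, z, method = "kendall")
  den <- sqrt((1 - txz^2) * (1 - tyz^2))
  if (!is.finite(den) || den == 0)
    return(list(tau = NA_real_, tau_xy = txy, tau_xz = txz, tau_yz = tyz,
                z_score = NA_real_, p = NA_real_, undefined = TRUE))
  tau <- (txy - txz * tyz) / den
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  zsc <- tau / se
  list(tau = tau, tau_xy = txy, tau_xz = txz, tau_yz = tyz,
       z_score = zsc, p = 2 * stats::pnorm(-abs(zsc)), undefined = FALSE)
}

#' Fisher enrichment over annotation terms
#'
#' Two-sided Fisher's exact test per term on the 2x2 table
#' (in_group, out_group; in_background, out_background), Bonferroni-corrected
#' for the number of terms.
#'
#' @param tables data.frame with columns term, in_group, out_group,
#'   in_background, out_background
#' @param n_terms Bonferroni denominator (defaults to `nrow(tables)`)
#' @return data.frame with odds_ratio, p, p_bonferroni per term
#' @export
fisher_enrichment <- function(tables, n_terms = nrow(tables)) {
  need <- c("term", "in_group", "out_group", "in_background", "out_background")
  stopifnot(all(need %in% names(tables)))
  cnt <- as.matrix(tables[, need[-1]])
  if (any(cnt < 0)) stop("negative counts")
  out <- tables
  out$odds_ratio <- out$p <- NA_real_
  for (i in seq_len(nrow(tables))) {
    m <- matrix(cnt[i, ], 2, 2, byrow = TRUE)
    ft <- stats::fisher.test(m, alternative = "two.sided")
    out$odds_ratio[i] <- unname(ft$estimate)
    out$p[i] <- ft$p.value
  }
  out$p_bonferroni <- pmin(1, out$p * n_terms)
  out
}

#' Permutation test for repeat-family insertion counts on a focal chromosome
#'
#' Places all insertions uniformly over the genome `n_sims` times and reports
#' the two-sided empirical p-value for the observed focal-chromosome count
#' (extremeness measured as absolute deviation from the expected count),
#' with add-one smoothing `(k + 1) / (n_sims + 1)`.
#'
#' @param n_insertions total insertions genome-wide
#' @param observed_focal observed insertions on the focal chromosome
#' @param chrom_lengths named vector of chromosome lengths
#' @param focal focal chromosome name
#' @param n_sims simulations
#' @param seed RNG seed (local)
#' @return list(p, expected, observed, sims summary)
#' @export
repeat_permutation <- function(n_insertions, observed_focal, chrom_lengths,
                               focal, n_sims = 1000L, seed = NULL) {
  if (n_insertions < 1) stop("need >= 1 insertion")
  if (!focal %in% names(chrom_lengths)) stop("focal chromosome absent: ", focal)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  pfocal <- chrom_lengths[[focal]] / sum(chrom_lengths)
  sims <- stats::rbinom(n_sims, n_insertions, pfocal)
  expected <- n_insertions * pfocal
  k <- sum(abs(sims - expected) >= abs(observed_focal - expected))
  list(p = (k + 1) / (n_sims + 1), expected = expected,
       observed = observed_focal, sim_mean = mean(sims), n_sims = n_sims)
}
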