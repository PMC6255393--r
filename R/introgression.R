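#' ABBA-BABA D statistic from diploid genotypes
#'
#' Frequency-weighted counting: with per-site derived-allele frequencies
#' `f_i = dosage_i / 2` in each of H1, H2, H3 (the outgroup fixed ancestral
#' by polarization), `ABBA = sum (1 - f1) f2 f3` and
#' `BABA = sum f1 (1 - f2) f3`; `D = (ABBA - BABA) / (ABBA + BABA)`.
#' A positive D indicates excess derived-allele sharing between H2 and H3.
#'
#' @param t [genotype_table()] (polarized internally against `outgroup`) or a
#'   [polarize()] result (then `outgroup` is ignored).
#' @param h1,h2,h3 sample ids for the two sister taxa and the candidate
#'   gene-flow partner
#' @param outgroup outgroup sample id (required for a genotype_table input)
#' @param sites optional data.frame(chrom, pos) restricting the computation
#'   (e.g. fourfold-degenerate positions)
#' @return list of class `dstat_result`: roles, ABBA, BABA, D, n_sites, plus
#'   per-site chrom/pos/abba/baba kept for block resampling
#' @export
abba_baba <- function(t, h1, h2, h3, outgroup = NULL, sites = NULL) {
  roles <- c(h1, h2, h3)
  if (anyDuplicated(c(roles, outgroup))) stop("duplicate sample roles")
  d <- if (inherits(t, "derived_table")) t else {
    if (is.null(outgroup)) stop("outgroup required for genotype_table input")
    polarize(t, outgroup)
  }
  if (any(!roles %in% colnames(d$deriv)))
    stop("samples not in table: ", paste(setdiff(roles, colnames(d$deriv)), collapse = ", "))
  keep <- rep(TRUE, nrow(d$sites))
  if (!is.null(sites)) {
    key <- paste(d$sites$chrom, d$sites$pos)
    keep <- key %in% paste(sites$chrom, sites$pos)
  }
  G <- d$deriv[keep, roles, drop = FALSE]
  ok <- stats::complete.cases(G)
  G <- G[ok, , drop = FALSE]
  f <- G / 2
  abba <- (1 - f[, 1]) * f[, 2] * f[, 3]
  baba <- f[, 1] * (1 - f[, 2]) * f[, 3]
  A <- sum(abba); B <- sum(baba)
  structure(list(h1 = h1, h2 = h2, h3 = h3, outgroup = outgroup,
                 ABBA = A, BABA = B,
                 D = if (A + B > 0) (A - B) / (A + B) else NA_real_,
                 undefined = A + B == 0, n_sites = nrow(G),
                 site_chrom = d$sites$chrom[keep][ok],
                 site_pos = d$sites$pos[keep][ok],
                 site_abba = abba, site_baba = baba),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D((%s,%s),%s): ABBA=%.2f BABA=%.2f D=%.4f", x$h1, x$h2, x$h3,
              x$ABBA, x$BABA, x$D))
  if (!is.null(x$Z)) cat(sprintf(" SE=%.4g Z=%.2f%s", x$SE, x$Z,
                                 if (isTRUE(x$significant)) " *" else ""))
  cat("\n"); invisible(x)
}

#' Block-bootstrap significance for a D statistic
#'
#' Cuts the genome into contiguous blocks of `block_size` bp, resamples
#' blocks with replacement to the original block count, recomputes D per
#' replicate, and reports SE (sd across replicates), Z = D/SE, and
#' significance at |Z| >= `z_crit`.
#'
#' @param r [abba_baba()] result
#' @param block_size block length in bp
#' @param n_boot bootstrap replicates
#' @param seed RNG seed (local to this call)
#' @param z_crit significance threshold on |Z|
#' @return `dstat_result` with SE, Z, significant, degenerate fields added
#' @export
block_significance <- function(r, block_size = 100000L, n_boot = 1000L,
                               seed = NULL, z_crit = 3) {
  blk <- paste(r$site_chrom, (r$site_pos - 1L) %/% block_size)
  ub <- unique(blk)
  if (length(ub) < 2) stop("need >= 2 non-empty blocks")
  bi <- match(blk, ub)
  A <- as.vector(tapply(r$site_abba, bi, sum))
  B <- as.vector(tapply(r$site_baba, bi, sum))
  nb <- length(ub)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
  As <- matrix(A[idx], nrow = n_boot) ; Bs <- matrix(B[idx], nrow = n_boot)
  Dstar <- (rowSums(As) - rowSums(Bs)) / (rowSums(As) + rowSums(Bs))
  SE <- stats::sd(Dstar)
  r$block_size <- block_size; r$n_boot <- n_boot
  r$SE <- SE
  r$degenerate <- SE == 0 || !is.finite(SE)
  r$Z <- if (r$degenerate) NA_real_ else r$D / SE
  r$significant <- !r$degenerate && abs(r$Z) >= z_crit
  r
}

#' Per-bin ABBA/BABA counts and D
#'
#' @param r [abba_baba()] result (site-level contributions retained)
#' @param bins data.frame(chrom, start, end), 0-based half-open,
#'   non-overlapping
#' @return data.frame per bin with ABBA, BABA, D, n_sites and an `empty` flag
#'   for bins with zero denominator
#' @export
windowed_d <- function(r, bins) {
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch)
  }
  out <- bins
  out$ABBA <- out$BABA <- 0; out$n_sites <- 0L
  for (i in seq_len(nrow(bins))) {
    sel <- r$site_chrom == bins$chrom[i] &
      r$site_pos > bins$start[i] & r$site_pos <= bins$end[i]
    out$ABBA[i] <- sum(r$site_abba[sel])
    out$BABA[i] <- sum(r$site_baba[sel])
    out$n_sites[i] <- sum(sel)
  }
  tot <- out$ABBA + out$BABA
  out$D <- ifelse(tot > 0, (out$ABBA - out$BABA) / tot, NA_real_)
  out$empty <- tot == 0
  out
}
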