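#' Pairwise nucleotide diversity between (or within) individuals
#'
#' Diversity is the percentage of pairwise sequence differences over the
#' callable genome. Within an individual (`a == b`) each heterozygous site
#' contributes one difference (individual heterozygosity). Between two
#' individuals the per-site contribution is the expected mismatch between one
#' random allele drawn from each: `d = (g_a (2 - g_b) + g_b (2 - g_a)) / 4`
#' for alt dosages in 0/1/2. Positions in the mask but absent from the table
#' are invariant and contribute zero differences; sites with a missing dosage
#' in either sample are excluded from numerator and denominator.
#'
#' @param t [genotype_table()]
#' @param a,b sample ids (equal for within-individual heterozygosity)
#' @param mask [callable_mask()] enumerating the callable genome
#' @param chrom optional chromosome to restrict to
#' @return list(scope, a, b, chrom, n_callable, n_diff, percent_diff)
#' @export
pairwise_diversity <- function(t, a, b, mask, chrom = NULL) {
  if (!a %in% t$samples$id || !b %in% t$samples$id)
    stop("unknown sample id: ", paste(setdiff(c(a, b), t$samples$id), collapse = ", "))
  sel <- rep(TRUE, nrow(t$sites))
  iv <- mask$intervals
  if (!is.null(chrom)) {
    sel <- t$sites$chrom == chrom
    iv <- iv[iv$chrom == chrom, , drop = FALSE]
  }
  total <- sum(iv$end - iv$start)
  if (total == 0) stop("zero callable overlap")
  sel <- sel & mask_contains(mask, t$sites$chrom, t$sites$pos)
  ga <- t$geno[sel, a]; gb <- t$geno[sel, b]
  miss <- is.na(ga) | is.na(gb)
  ga <- ga[!miss]; gb <- gb[!miss]
  d <- if (a == b) as.numeric(ga == 1L) else (ga * (2 - gb) + gb * (2 - ga)) / 4
  n_callable <- total - sum(miss)
  list(scope = if (a == b) "sample" else "sample-pair", a = a, b = b,
       chrom = chrom %||% "genome", n_callable = n_callable,
       n_diff = sum(d), percent_diff = 100 * sum(d) / n_callable)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Diversity for all sample pairs
#' @inheritParams pairwise_diversity
#' @param pairs "all" (including within-individual), "within" (self pairs
#'   only) or "between"
#' @return data.frame with one row per pair
#' @export
diversity_table <- function(t, mask, pairs = c("all", "within", "between"),
                            chrom = NULL) {
  pairs <- match.arg(pairs)
  ids <- t$samples$id
  out <- list(); k <- 0
  for (i in seq_along(ids)) for (j in i:length(ids)) {
    if (pairs == "within" && i != j) next
    if (pairs == "between" && i == j) next
    r <- pairwise_diversity(t, ids[i], ids[j], mask, chrom)
    k <- k + 1
    out[[k]] <- data.frame(sample_a = ids[i], sample_b = ids[j],
                           chrom = r$chrom, n_callable = r$n_callable,
                           n_diff = r$n_diff, pct = r$percent_diff,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Hudson-style FST between two regions
#'
#' `FST = 1 - Hw / Hb` where `Hw` is the mean pairwise diversity within
#' regions (the two regions weighted equally; within-individual
#' heterozygosity is used when a region holds a single sample) and `Hb` the
#' mean diversity over all between-region pairs.
#'
#' @param t [genotype_table()]
#' @param regionA,regionB character vectors of sample ids
#' @param mask [callable_mask()]
#' @param chrom optional chromosome restriction
#' @return list(fst, Hw, Hb, flagged)
#' @export
hudson_fst <- function(t, regionA, regionB, mask, chrom = NULL) {
  if (length(regionA) < 1 || length(regionB) < 1) stop("empty region")
  within_mean <- function(ids) {
    if (length(ids) == 1)
      return(pairwise_diversity(t, ids, ids, mask, chrom)$percent_diff)
    v <- c()
    for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j)
      v <- c(v, pairwise_diversity(t, ids[i], ids[j], mask, chrom)$percent_diff)
    mean(v)
  }
  Hw <- mean(c(within_mean(regionA), within_mean(regionB)))
  vb <- c()
  for (a in regionA) for (b in regionB)
    vb <- c(vb, pairwise_diversity(t, a, b, mask, chrom)$percent_diff)
  Hb <- mean(vb)
  if (Hb == 0)
    return(list(fst = NA_real_, Hw = Hw, Hb = Hb, flagged = TRUE))
  list(fst = 1 - Hw / Hb, Hw = Hw, Hb = Hb, flagged = FALSE)
}

#' Detect runs of near-homozygosity in one sample
#'
#' Tiles each chromosome with windows of `window_bp`, computes the sample's
#' heterozygosity (percent of callable bp heterozygous) per window, flags
#' windows strictly below `threshold_pct`, and merges adjacent flagged windows
#' into runs. Windows with under 10 percent callable coverage are reported as
#' no-call and break runs.
#'
#' @param t [genotype_table()]
#' @param s sample id
#' @param mask [callable_mask()]
#' @param window_bp window size in bp
#' @param threshold_pct heterozygosity threshold (percent, strict `<`)
#' @return list(runs = data.frame(chrom, start, end), windows = per-window
#'   data.frame with status in {run, normal, no_call})
#' @export
homozygosity_runs <- function(t, s, mask, window_bp = 100000L, threshold_pct = 0.1) {
  if (window_bp <= 0) stop("window_bp must be positive")
  iv <- mask$intervals
  win <- list(); k <- 0
  for (ch in unique(iv$chrom)) {
    ext <- max(iv$end[iv$chrom == ch])
    starts <- seq(0L, ext - 1L, by = window_bp)
    on_ch <- t$sites$chrom == ch
    g <- t$geno[on_ch, s]
    p <- t$sites$pos[on_ch]
    for (st in starts) {
      en <- min(st + window_bp, ext)
      bp <- mask_bp_in_window(mask, ch, st, en)
      in_w <- p > st & p <= en
      het <- sum(g[in_w] == 1L, na.rm = TRUE)
      status <- if (bp < 0.1 * window_bp) "no_call"
        else if (100 * het / bp < threshold_pct) "run" else "normal"
      k <- k + 1
      win[[k]] <- data.frame(chrom = ch, start = st, end = en, callable = bp,
                             het_sites = het,
                             het_pct = if (bp > 0) 100 * het / bp else NA_real_,
                             status = status, stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, win)
  runs <- list(); k <- 0
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    r <- rle(w$status == "run")
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    for (i in seq_along(r$values)) if (r$values[i]) {
      k <- k + 1
      runs[[k]] <- data.frame(chrom = ch, start = w$start[idx_start[i]],
                              end = w$end[idx_end[i]], stringsAsFactors = FALSE)
    }
  }
  list(runs = if (k > 0) do.call(rbind, runs)
              else data.frame(chrom = character(), start = integer(), end = integer()),
       windows = windows)
}
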