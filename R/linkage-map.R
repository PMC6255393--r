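#' Assign grandparental bin genotypes from diagnostic read ratios
#'
#' For each F2 individual, parent of origin, and genomic bin, the ratio of
#' reads carrying a diagnostic allele to reads that could carry one
#' determines the bin's grandparental assignment: a ratio in `[lo, hi]`
#' assigns the bin to the parent carrying the diagnostic allele
#' (heterozygous carrier, expected ratio 0.5); a ratio in `[review_lo, lo)`
#' is flagged for review (possible recombination breakpoint or reference
#' discordance); below `review_lo` the bin goes to the other parent. Ratios
#' above `hi` are treated as assignable to the diagnostic parent with a
#' warning (the over-represented side). Bins with no informative reads are
#' no-calls.
#'
#' @param counts data.frame with columns f2_id, parent, chrom, start, end,
#'   observed, possible (start/end 0-based half-open)
#' @param lo,hi assignment band on the diagnostic read ratio
#' @param review_lo lower bound of the review band
#' @return the input with `ratio` and `assignment` in
#'   {parent1, parent2, review, no_call} added (`parent1` = the parent
#'   carrying the diagnostic allele); class `bin_genotype_table`
#' @export
assign_bin_genotypes <- function(counts, lo = 0.4, hi = 0.6, review_lo = 0.1) {
  need <- c("f2_id", "parent", "chrom", "start", "end", "observed", "possible")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$observed < 0 | counts$possible < 0)) stop("negative read counts")
  if (any(counts$observed > counts$possible)) stop("observed exceeds possible")
  ratio <- ifelse(counts$possible > 0, counts$observed / counts$possible, NA_real_)
  assignment <- rep("no_call", nrow(counts))
  assignment[!is.na(ratio) & ratio >= lo] <- "parent1"
  assignment[!is.na(ratio) & ratio >= review_lo & ratio < lo] <- "review"
  assignment[!is.na(ratio) & ratio < review_lo] <- "parent2"
  if (any(!is.na(ratio) & ratio > hi))
    warning(sum(!is.na(ratio) & ratio > hi),
            " bins with ratio > ", hi, " assigned to the diagnostic parent")
  counts$ratio <- ratio
  counts$assignment <- assignment
  class(counts) <- c("bin_genotype_table", class(counts))
  counts
}

#' Per-bin recombination rates from bin genotypes
#'
#' A recombination event is a change of assigned grandparent between
#' consecutive assigned bins along a chromosome within one F2 x parent
#' haplotype; review and no-call bins are skipped and an event across them is
#' attributed to the first assigned downstream bin. The rate is
#' `(events / n_haploid) * 100 / bin size in Mb` (cM/Mb).
#'
#' @param bg [assign_bin_genotypes()] result
#' @param n_haploid number of haploid genomes assessed
#' @return data.frame per bin: chrom, start, end, size_Mb, events, n_haploid,
#'   rate_cM_Mb
#' @export
recombination_rates <- function(bg, n_haploid = 648L) {
  bins <- unique(bg[, c("chrom", "start", "end")])
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("bins overlap or are unordered on ", ch)
  }
  key <- paste(bins$chrom, bins$start)
  events <- stats::setNames(numeric(nrow(bins)), key)
  for (grp in split(seq_len(nrow(bg)), paste(bg$f2_id, bg$parent, bg$chrom))) {
    g <- bg[grp, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    g <- g[g$assignment %in% c("parent1", "parent2"), , drop = FALSE]
    if (nrow(g) < 2) next
    chg <- which(g$assignment[-1] != g$assignment[-nrow(g)]) + 1
    if (length(chg) > 0) {
      k <- paste(g$chrom[chg], g$start[chg])
      for (kk in k) events[kk] <- events[kk] + 1
    }
  }
  bins$size_Mb <- (bins$end - bins$start) / 1e6
  bins$events <- unname(events[key])
  bins$n_haploid <- n_haploid
  bins$rate_cM_Mb <- (bins$events / n_haploid) * 100 / bins$size_Mb
  bins
}
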