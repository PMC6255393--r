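#' Polarize ingroup variants against an outgroup
#'
#' Sites where the outgroup individual is homozygous define the ancestral
#' allele; the other allele is derived. Sites are dropped when the outgroup is
#' heterozygous or missing, when the outgroup's allele is absent from the
#' ingroup (the ingroup would be fixed derived with no ancestral copy
#' observed), or when the site is monomorphic in the ingroup after
#' polarization.
#'
#' @param t [genotype_table()]
#' @param outgroup sample id of the outgroup individual
#' @param drop_fixed_derived drop sites where every ingroup sample is
#'   homozygous derived (default TRUE; such sites carry no sharing signal)
#' @return object of class `derived_table`: sites (chrom, pos,
#'   ancestral_allele, derived_allele), `deriv` matrix of derived-allele
#'   dosage for ingroup samples, `samples` (ingroup sample table)
#' @export
polarize <- function(t, outgroup, drop_fixed_derived = TRUE) {
  if (!outgroup %in% t$samples$id) stop("outgroup sample not in table: ", outgroup)
  og <- t$geno[, outgroup]
  in_ids <- setdiff(t$samples$id, outgroup)
  G <- t$geno[, in_ids, drop = FALSE]
  keep <- !is.na(og) & og %in% c(0L, 2L) & !t$sites$is_multiallelic
  # orient dosages to the derived allele
  flip <- og == 2L
  D <- G
  D[flip & keep, ] <- 2L - G[flip & keep, , drop = FALSE]
  anc <- ifelse(flip, t$sites$alt, t$sites$ref)
  der <- ifelse(flip, t$sites$ref, t$sites$alt)
  # outgroup allele must be present in the ingroup: some sample carries
  # the ancestral allele (dosage < 2 for at least one called sample)
  anc_seen <- apply(D, 1, function(g) any(!is.na(g) & g < 2L))
  poly <- apply(D, 1, function(g) any(!is.na(g) & g > 0L))
  keep <- keep & poly & (if (drop_fixed_derived) anc_seen else TRUE)
  structure(list(sites = data.frame(chrom = t$sites$chrom[keep],
                                    pos = t$sites$pos[keep],
                                    ancestral_allele = anc[keep],
                                    derived_allele = der[keep],
                                    stringsAsFactors = FALSE),
                 deriv = D[keep, , drop = FALSE],
                 samples = t$samples[t$samples$id %in% in_ids, , drop = FALSE]),
            class = "derived_table")
}

#' @export
print.derived_table <- function(x, ...) {
  cat("derived_table:", nrow(x$sites), "polarized sites x",
      nrow(x$samples), "ingroup samples\n")
  invisible(x)
}

#' Classify derived-variant sharing depth per species
#'
#' For every (species, site) with derived dosage > 0 the variant is `private`
#' when no other species carries it, `within_region` when all other carriers
#' are in the species' own region, and `two_regions` / `three_regions` by the
#' number of distinct regions (including the species' own) that carry the
#' derived allele. Presence/absence coding (dosage > 0).
#'
#' @param d [polarize()] result
#' @param regions optional named vector species -> region; defaults to the
#'   region labels stored in the table
#' @return list(counts, proportions): matrices species x
#'   {private, within_region, two_regions, three_regions}
#' @export
sharing_classification <- function(d, regions = NULL) {
  ids <- d$samples$id
  if (is.null(regions)) regions <- stats::setNames(d$samples$region, ids)
  if (any(!ids %in% names(regions)))
    stop("species missing region label: ",
         paste(setdiff(ids, names(regions)), collapse = ", "))
  if (length(unique(regions[ids])) < 2) stop("need >= 2 regions")
  P <- !is.na(d$deriv) & d$deriv > 0L   # sites x species presence
  cats <- c("private", "within_region", "two_regions", "three_regions")
  counts <- matrix(0L, length(ids), 4, dimnames = list(ids, cats))
  reg <- regions[ids]
  for (s in seq_along(ids)) {
    has <- P[, s]
    if (!any(has)) next
    others <- P[has, -s, drop = FALSE]
    n_other <- rowSums(others)
    # regions carrying the allele (among carriers other than s), plus s's own
    other_regs <- apply(others, 1, function(z) unique(reg[-s][z]))
    nreg <- vapply(other_regs, function(r) length(unique(c(r, reg[s]))), integer(1))
    cat_i <- ifelse(n_other == 0, 1L, ifelse(nreg == 1, 2L, ifelse(nreg == 2, 3L, 4L)))
    counts[s, ] <- tabulate(cat_i, 4)
  }
  proportions <- counts / pmax(rowSums(counts), 1)
  list(counts = counts, proportions = proportions)
}

#' Topology support from derived-variant sharing in a species trio
#'
#' A polarized site is informative for trio (a, b, c) when exactly two of the
#' three species carry the derived allele; the carrying pair supports the
#' topology grouping them: T1 = ((b,c),a), T2 = ((a,c),b), T3 = ((a,b),c).
#'
#' @param d [polarize()] result
#' @param trio character vector of three sample ids (a, b, c)
#' @param weighted use dosage-weighted contributions
#'   `f_i f_j (1 - f_k)` with `f = dosage / 2` instead of presence counts
#' @return list(trio, counts, proportions, n_informative)
#' @export
topology_support <- function(d, trio, weighted = FALSE) {
  stopifnot(length(trio) == 3)
  if (any(!trio %in% colnames(d$deriv)))
    stop("trio samples not in table: ",
         paste(setdiff(trio, colnames(d$deriv)), collapse = ", "))
  G <- d$deriv[, trio, drop = FALSE]
  ok <- stats::complete.cases(G)
  G <- G[ok, , drop = FALSE]
  if (weighted) {
    f <- G / 2
    w <- c(T1 = sum(f[, 2] * f[, 3] * (1 - f[, 1])),
           T2 = sum(f[, 1] * f[, 3] * (1 - f[, 2])),
           T3 = sum(f[, 1] * f[, 2] * (1 - f[, 3])))
    tot <- sum(w)
    return(list(trio = trio, counts = w,
                proportions = if (tot > 0) w / tot else rep(NA_real_, 3),
                n_informative = tot, empty = tot == 0))
  }
  P <- G > 0L
  npres <- rowSums(P)
  inf <- npres == 2L
  Pi <- P[inf, , drop = FALSE]
  counts <- c(T1 = sum(Pi[, 2] & Pi[, 3]),
              T2 = sum(Pi[, 1] & Pi[, 3]),
              T3 = sum(Pi[, 1] & Pi[, 2]))
  n <- sum(inf)
  list(trio = trio, counts = counts,
       proportions = if (n > 0) counts / n else rep(NA_real_, 3),
       n_informative = n, empty = n == 0)
}
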