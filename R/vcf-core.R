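#' Load a multi-sample VCF into a genotype table
#'
#' Parses GT (dosage of non-reference alleles, phase ignored), DP and, when
#' present, AD fields. Multiallelic records are retained but flagged so the
#' site filters can remove them; indel records are flagged from REF/ALT
#' lengths.
#'
#' @param path VCF file (plain or bgzip/gzip).
#' @param region_map named character vector or list mapping every VCF sample
#'   id to a region label (e.g. `c(oxy = "AS", ...)`).
#' @return [genotype_table()]
#' @export
load_vcf <- function(path, region_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- colnames(v@gt)[-1]
  region_map <- unlist(region_map)
  missing <- setdiff(ids, names(region_map))
  if (length(missing) > 0)
    stop("VCF samples absent from region_map: ", paste(missing, collapse = ", "))
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt <- fx$ALT
  is_multi <- grepl(",", alt, fixed = TRUE)
  alt1 <- sub(",.*", "", alt)
  is_indel <- nchar(fx$REF) != 1L | nchar(alt1) != 1L
  # for multiallelic records any allele length difference marks an indel
  if (any(is_multi)) {
    multi_alleles <- strsplit(alt[is_multi], ",", fixed = TRUE)
    is_indel[is_multi] <- is_indel[is_multi] |
      vapply(multi_alleles, function(a) any(nchar(a) != 1L), logical(1))
  }
  sites <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                      ref = fx$REF, alt = alt, is_indel = is_indel,
                      is_multiallelic = is_multi, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = count of non-reference alleles, phase-insensitive
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(clean, names(known))
  dose[] <- known[idx]
  other <- is.na(idx) & !is.na(clean) & !grepl("\\.", clean)
  if (any(other)) { # multiallelic genotypes: count any non-zero allele
    dose[other] <- vapply(strsplit(clean[other], "/", fixed = TRUE),
                          function(a) sum(a != "0"), integer(1))
  }
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp) || all(is.na(dp))) dp <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad) && !all(is.na(ad))) {
    ad_ref <- suppressWarnings(matrix(as.integer(sub(",.*", "", ad)), nrow(ad), ncol(ad)))
    ad_alt <- suppressWarnings(matrix(as.integer(sub("^[^,]*,", "", sub("(,[^,]*),.*", "\\1", ad))),
                                      nrow(ad), ncol(ad)))
  }
  samples <- data.frame(id = ids, region = unname(region_map[ids]),
                        stringsAsFactors = FALSE)
  genotype_table(sites, samples, dose, matrix(as.integer(round(dp)), nrow(dp), ncol(dp)),
                 ad_ref, ad_alt)
}

#' Site filter configuration
#'
#' @param min_depth minimum per-sample read depth for a site to be callable.
#' @param cov_log_bound per-sample bound on `|log(depth / median depth)|`
#'   (default 0.5; 0.15 for a stringent variant of the coverage filter).
#' @param log_base base of the logarithm used by depth-ratio filters.
#' @param indel_pad bp around an indel record within which SNPs are dropped.
#' @param het_balance_bound bound on `|log10(ref reads / alt reads)|` for
#'   heterozygous calls (see [allele_balance_filter()]).
#' @param require_all_called drop sites with any missing genotype.
#' @return list of class `filter_config`
#' @export
filter_config <- function(min_depth = 15L, cov_log_bound = 0.5, log_base = 10,
                          indel_pad = 10L, het_balance_bound = 0.3,
                          require_all_called = TRUE) {
  if (cov_log_bound <= 0 || log_base <= 0 || het_balance_bound <= 0)
    stop("filter bounds must be positive")
  if (indel_pad < 0) stop("indel_pad must be >= 0")
  structure(list(min_depth = min_depth, cov_log_bound = cov_log_bound,
                 log_base = log_base, indel_pad = indel_pad,
                 het_balance_bound = het_balance_bound,
                 require_all_called = require_all_called),
            class = "filter_config")
}

#' Apply site-level filters to a genotype table
#'
#' Removes, in fixed order: multiallelic sites; indels and all sites within
#' `indel_pad` bp of an indel; sites inside repeat intervals; sites with any
#' sample depth below `min_depth`; sites where any sample's log depth ratio to
#' its median depth exceeds `cov_log_bound` in absolute value; and (when
#' `require_all_called`) sites not genotyped in every sample. Each removed
#' site is attributed to the first filter it fails. Per-sample median depth is
#' computed over all input sites before any filtering.
#'
#' @param t [genotype_table()]
#' @param cfg [filter_config()]
#' @param repeats data.frame(chrom, start, end), 0-based half-open repeat
#'   intervals (e.g. from [read_bed()]); NULL for none.
#' @return list with elements `table` (surviving sites), `mask`
#'   ([callable_mask()] of surviving positions) and `report` (`filter_report`:
#'   ordered per-filter removal counts).
#' @export
apply_site_filters <- function(t, cfg = filter_config(), repeats = NULL) {
  if (nrow(t$sites) == 0) stop("empty genotype table")
  n <- nrow(t$sites)
  med <- apply(t$depth, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) stop("per-sample median depth not computable")
  fail <- rep(NA_character_, n)
  mark <- function(bad, name) {
    new <- bad & is.na(fail)
    fail[new] <<- name
  }
  mark(t$sites$is_multiallelic, "multiallelic")
  # indels and their neighborhoods
  ind <- which(t$sites$is_indel)
  near <- t$sites$is_indel
  if (length(ind) > 0 && cfg$indel_pad > 0) {
    for (ch in unique(t$sites$chrom[ind])) {
      on_ch <- t$sites$chrom == ch
      ip <- t$sites$pos[ind][t$sites$chrom[ind] == ch]
      p <- t$sites$pos[on_ch]
      hit <- rep(FALSE, length(p))
      for (q in ip) hit <- hit | (abs(p - q) <= cfg$indel_pad)
      near[on_ch] <- near[on_ch] | hit
    }
  }
  mark(near, "indel_pad")
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rm_mask <- callable_mask(repeats)
    mark(mask_contains(rm_mask, t$sites$chrom, t$sites$pos), "repeat")
  } else mark(rep(FALSE, n), "repeat")
  dp_bad <- apply(t$depth, 1, function(d) any(is.na(d) | d < cfg$min_depth))
  mark(dp_bad, "depth")
  lr <- log(sweep(t$depth, 2, med, "/"), base = cfg$log_base)
  cov_bad <- apply(lr, 1, function(x) any(!is.finite(x) | abs(x) > cfg$cov_log_bound))
  mark(cov_bad, "coverage")
  if (cfg$require_all_called)
    mark(apply(t$geno, 1, anyNA), "not_all_called")
  else mark(rep(FALSE, n), "not_all_called")

  keep <- is.na(fail)
  counts <- table(factor(fail, levels = c("multiallelic", "indel_pad", "repeat",
                                          "depth", "coverage", "not_all_called")))
  report <- structure(list(removed = as.integer(counts),
                           filters = names(counts),
                           sites_in = n, sites_out = sum(keep)),
                      class = "filter_report")
  out <- subset_sites(t, keep)
  list(table = out, mask = mask_from_sites(out), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$sites_in, "sites in,", x$sites_out, "sites out\n")
  for (i in seq_along(x$filters))
    cat(sprintf("  %-16s %d\n", x$filters[i], x$removed[i]))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report filter_report
#' @param path output TSV
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(data.frame(filter = c(report$filters, "sites_in", "sites_out"),
                                removed = c(report$removed, report$sites_in, report$sites_out)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mask heterozygous calls with unbalanced allele depths
#'
#' Heterozygous genotypes whose log10 ratio of reference to alternate read
#' counts falls outside `[-bound, bound]` are set to missing; homozygous calls
#' are untouched. Requires per-allele depths for all heterozygous calls.
#'
#' @param t [genotype_table()] with `ad_ref`/`ad_alt`
#' @param bound bound on |log10(ref reads / alt reads)|
#' @return filtered genotype_table
#' @export
allele_balance_filter <- function(t, bound = 0.3) {
  het <- !is.na(t$geno) & t$geno == 1L
  if (is.null(t$ad_ref) || is.null(t$ad_alt))
    stop("allele depths required for allele-balance filtering")
  need <- het & (is.na(t$ad_ref) | is.na(t$ad_alt))
  if (any(need)) {
    bad <- unique(t$sites$pos[which(rowSums(need) > 0)])
    stop("missing allele depths for het calls at sites: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  lr <- log10(t$ad_ref / t$ad_alt)
  drop <- het & (!is.finite(lr) | abs(lr) > bound)
  t$geno[drop] <- NA_integer_
  t
}

#' Write a genotype table to VCF
#'
#' Emits a minimal standards-compliant VCF 4.2 with GT, DP and (when present)
#' AD genotype fields.
#'
#' @param t genotype_table
#' @param path output path (plain text; use a `.vcf` extension)
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   header.
#' @export
write_vcf <- function(t, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=radpop"), con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", t$samples$id), collapse = "\t"), con)
  has_ad <- !is.null(t$ad_ref)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[t$geno + 1L], nrow(t$geno))
  gt_str[is.na(t$geno)] <- "./."
  dp_str <- matrix(as.character(t$depth), nrow(t$depth))
  dp_str[is.na(t$depth)] <- "."
  if (has_ad) {
    ad_str <- matrix(paste0(t$ad_ref, ",", t$ad_alt), nrow(t$geno))
    ad_str[is.na(t$ad_ref) | is.na(t$ad_alt)] <- ".,."
    cells <- matrix(paste(gt_str, dp_str, ad_str, sep = ":"), nrow(t$geno))
    fmt <- "GT:DP:AD"
  } else {
    cells <- matrix(paste(gt_str, dp_str, sep = ":"), nrow(t$geno))
    fmt <- "GT:DP"
  }
  body <- cbind(t$sites$chrom, t$sites$pos, ".", t$sites$ref, t$sites$alt,
                ".", "PASS", ".", fmt, cells)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
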