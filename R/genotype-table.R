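#' Construct a genotype table
#'
#' The central container for multi-sample diploid genotype data: a sites table,
#' a sample table with geographic region labels, and sites-by-samples matrices
#' of alt-allele dosage and read depth (plus optional per-allele depths).
#' Internally all per-site coordinates are 1-based VCF positions; interval
#' containers ([callable_mask()]) use 0-based half-open coordinates.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `is_indel` (logical), and optionally `is_multiallelic` (logical; for
#'   multiallelic records `alt` holds the comma-separated allele list).
#' @param samples data.frame with columns `id` and `region`; region labels are
#'   free strings, conventionally `"NA"`, `"EU"`, `"AS"`, `"OUT"`.
#' @param geno integer matrix (sites x samples) of alt-allele dosage in
#'   0/1/2, `NA` for missing calls.
#' @param depth integer matrix (sites x samples) of total read depth; `NA`
#'   where unrecorded.
#' @param ad_ref,ad_alt optional integer matrices of per-allele read depths
#'   (reference and alternate) backing heterozygous calls.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, samples, geno, depth, ad_ref = NULL, ad_alt = NULL) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  need <- c("chrom", "pos", "ref", "alt", "is_indel")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  if (is.null(sites$is_multiallelic)) sites$is_multiallelic <- FALSE
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  geno <- as.matrix(geno); depth <- as.matrix(depth)
  if (nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples))
    stop("geno dimensions do not match sites x samples")
  if (!all(dim(depth) == dim(geno))) stop("depth dimensions do not match geno")
  # positions strictly increasing within chromosome
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", ch)
  }
  colnames(geno) <- colnames(depth) <- samples$id
  if (!is.null(ad_ref)) {
    ad_ref <- as.matrix(ad_ref); ad_alt <- as.matrix(ad_alt)
    colnames(ad_ref) <- colnames(ad_alt) <- samples$id
  }
  structure(list(sites = sites, samples = samples, geno = geno, depth = depth,
                 ad_ref = ad_ref, ad_alt = ad_alt),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$samples$region)),
                                  table(x$samples$region)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a genotype table by site index
#' @param t genotype_table
#' @param i logical or integer site index
#' @return genotype_table restricted to the selected sites
#' @export
subset_sites <- function(t, i) {
  genotype_table(t$sites[i, , drop = FALSE], t$samples,
                 t$geno[i, , drop = FALSE], t$depth[i, , drop = FALSE],
                 if (!is.null(t$ad_ref)) t$ad_ref[i, , drop = FALSE],
                 if (!is.null(t$ad_alt)) t$ad_alt[i, , drop = FALSE])
}

#' Construct a callable mask
#'
#' A per-chromosome set of disjoint genomic intervals defining the part of the
#' genome in which genotypes are considered reliably called. Stored 0-based
#' half-open; written to BED in the same convention.
#'
#' @param intervals data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive). Overlapping or adjacent intervals are merged.
#' @return Object of class `callable_mask` with a `total_callable` field.
#' @export
callable_mask <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0) {
    if (any(intervals$end <= intervals$start)) stop("empty or inverted interval")
    intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
    out <- vector("list", length(unique(intervals$chrom)))
    k <- 0
    for (ch in unique(intervals$chrom)) {
      iv <- intervals[intervals$chrom == ch, , drop = FALSE]
      s <- iv$start; e <- iv$end
      keep_s <- s[1]; keep_e <- e[1]; res_s <- c(); res_e <- c()
      if (nrow(iv) > 1) for (j in 2:nrow(iv)) {
        if (s[j] <= keep_e) keep_e <- max(keep_e, e[j])
        else { res_s <- c(res_s, keep_s); res_e <- c(res_e, keep_e); keep_s <- s[j]; keep_e <- e[j] }
      }
      res_s <- c(res_s, keep_s); res_e <- c(res_e, keep_e)
      k <- k + 1
      out[[k]] <- data.frame(chrom = ch, start = res_s, end = res_e,
                             stringsAsFactors = FALSE)
    }
    intervals <- do.call(rbind, out)
  }
  structure(list(intervals = intervals,
                 total_callable = sum(intervals$end - intervals$start)),
            class = "callable_mask")
}

#' @export
print.callable_mask <- function(x, ...) {
  cat("callable_mask:", nrow(x$intervals), "intervals,",
      x$total_callable, "bp callable\n")
  invisible(x)
}

#' Build a callable mask from the sites of a genotype table
#'
#' Each site becomes a 1-bp interval; adjacent sites merge.
#' @param t genotype_table
#' @return callable_mask
#' @export
mask_from_sites <- function(t) {
  callable_mask(data.frame(chrom = t$sites$chrom, start = t$sites$pos - 1L,
                           end = t$sites$pos, stringsAsFactors = FALSE))
}

#' Is each position inside the mask?
#' @param mask callable_mask
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @return logical vector
#' @export
mask_contains <- function(mask, chrom, pos) {
  res <- logical(length(pos))
  iv <- mask$intervals
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(ivc) == 0) next
    # pos-1 in [start, end)
    idx <- findInterval(pos[sel] - 1L, ivc$start)
    hit <- idx >= 1 & (pos[sel] - 1L) < ivc$end[pmax(idx, 1L)]
    res[sel] <- hit
  }
  res
}

#' Callable basepairs of the mask within a genomic window
#' @param mask callable_mask
#' @param chrom chromosome
#' @param start,end window, 0-based half-open
#' @return integer bp
#' @export
mask_bp_in_window <- function(mask, chrom, start, end) {
  iv <- mask$intervals
  iv <- iv[iv$chrom == chrom & iv$end > start & iv$start < end, , drop = FALSE]
  if (nrow(iv) == 0) return(0L)
  sum(pmin(iv$end, end) - pmax(iv$start, start))
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open; returned unchanged in that convention.
#' @param path BED file
#' @return data.frame(chrom, start, end)
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write intervals (or a callable mask) to BED
#' @param x callable_mask or data.frame(chrom, start, end) 0-based half-open
#' @param path output file
#' @export
write_bed <- function(x, path) {
  iv <- if (inherits(x, "callable_mask")) x$intervals else x
  utils::write.table(iv[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
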