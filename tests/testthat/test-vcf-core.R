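write_mini_vcf <- function(lines, samples = c("a", "b")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}

test_that("load_vcf parses records, dosages and missing genotypes", {
  p <- write_mini_vcf(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20\t1/1:30",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:DP\t0|0:25\t./.:10",
    "chr1\t300\t.\tT\tA,G\t.\tPASS\t.\tGT:DP\t1/2:20\t0/0:20"))
  tab <- load_vcf(p, c(a = "NA", b = "EU"))
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(unname(tab$geno[1, ]), c(1L, 2L))
  expect_equal(unname(tab$geno[2, ]), c(0L, NA_integer_))  # ./. is missing
  expect_true(tab$sites$is_multiallelic[3])
  expect_false(any(tab$sites$is_multiallelic[1:2]))
  expect_equal(unname(tab$depth[1, ]), c(20L, 30L))
})

test_that("load_vcf rejects samples absent from the region map", {
  p <- write_mini_vcf("chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20\t1/1:30")
  expect_error(load_vcf(p, c(a = "NA")), "absent from region_map")
})

test_that("site filters remove the hand-enumerated toy sites with per-filter attribution", {
  # 1 multiallelic, 1 indel plus a SNP 8 bp away, 1 repeat-masked,
  # 1 low-depth, 6 clean -> 6 survivors
  g <- matrix(1L, 11, 2, dimnames = list(NULL, c("a", "b")))
  pos <- c(100L, 200L, 208L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L)
  tab <- make_tab(g, pos = pos,
                  is_indel = c(FALSE, TRUE, rep(FALSE, 9)),
                  is_multi = c(TRUE, rep(FALSE, 10)))
  tab$depth[6, 1] <- 14L  # below min depth in one sample
  repeats <- data.frame(chrom = "chr1", start = 399L, end = 400L)  # site 400
  res <- apply_site_filters(tab, filter_config(min_depth = 15L, cov_log_bound = 5),
                            repeats)
  expect_equal(res$report$sites_out, 6L)
  rem <- setNames(res$report$removed, res$report$filters)
  expect_equal(rem[["multiallelic"]], 1L)
  expect_equal(rem[["indel_pad"]], 2L)   # the indel and the SNP 8 bp away
  expect_equal(rem[["repeat"]], 1L)
  expect_equal(rem[["depth"]], 1L)
  expect_equal(rem[["coverage"]], 0L)
  expect_equal(setdiff(pos, res$table$sites$pos),
               c(100L, 200L, 208L, 400L, 500L))
})

test_that("minimum depth of 15 in all samples removes a depth-14 site", {
  g <- matrix(0:1, 4, 2, dimnames = list(NULL, c("a", "b")))
  tab <- make_tab(g, depth = 20L)
  tab$depth[2, 2] <- 14L
  res <- apply_site_filters(tab, filter_config(min_depth = 15L, cov_log_bound = 5))
  rem <- setNames(res$report$removed, res$report$filters)
  expect_equal(rem[["depth"]], 1L)
  expect_false(20L %in% res$table$sites$pos)
})

test_that("filtering is idempotent and the surviving set is order-invariant", {
  fx <- radsim_fixture()
  again <- apply_site_filters(fx$tab, filter_config())
  expect_equal(again$table$sites, fx$tab$sites)
  expect_equal(again$report$sites_in, again$report$sites_out)
  # mask total equals surviving site count (sites enumerate assayed positions)
  expect_equal(fx$site_mask$total_callable, nrow(fx$tab$sites))
})

test_that("coverage filter removes sites off the per-sample median by the log bound", {
  g <- matrix(1L, 5, 2, dimnames = list(NULL, c("a", "b")))
  tab <- make_tab(g, depth = 50L)
  tab$depth[3, 1] <- 200L  # log10(200/50) = 0.602 > 0.5
  res <- apply_site_filters(tab, filter_config(min_depth = 5L, cov_log_bound = 0.5))
  rem <- setNames(res$report$removed, res$report$filters)
  expect_equal(rem[["coverage"]], 1L)
})

test_that("allele-balance filter drops only unbalanced heterozygous calls", {
  g <- matrix(c(1L, 1L, 2L), 3, 1, dimnames = list(NULL, "a"))
  tab <- make_tab(g, ad = TRUE)
  tab$ad_ref[1, 1] <- 10L; tab$ad_alt[1, 1] <- 10L   # balanced het
  tab$ad_ref[2, 1] <- 20L; tab$ad_alt[2, 1] <- 5L    # log10(4) = 0.602 > 0.3
  tab$ad_ref[3, 1] <- 0L;  tab$ad_alt[3, 1] <- 50L   # hom: untouched
  out <- allele_balance_filter(tab, bound = 0.3)
  expect_equal(unname(out$geno[, 1]), c(1L, NA, 2L))
})

test_that("allele-balance filter demands allele depths for het calls", {
  g <- matrix(1L, 2, 1, dimnames = list(NULL, "a"))
  tab <- make_tab(g, ad = TRUE)
  tab$ad_ref[1, 1] <- NA
  expect_error(allele_balance_filter(tab), "missing allele depths")
})

test_that("VCF writer round-trips through the reader", {
  fx <- radsim_fixture()
  sub <- subset_sites(fx$raw, 1:50)
  p <- tempfile(fileext = ".vcf")
  write_vcf(sub, p)
  back <- load_vcf(p, setNames(sub$samples$region, sub$samples$id))
  expect_equal(back$sites$pos, sub$sites$pos)
  # biallelic SNP dosages survive the round trip
  bi <- !sub$sites$is_multiallelic & !sub$sites$is_indel
  expect_equal(back$geno[bi, ], sub$geno[bi, ])
  expect_equal(back$depth, sub$depth)
})

test_that("BED masks interconvert with interval merging", {
  m <- callable_mask(data.frame(chrom = "chr1", start = c(0L, 10L, 30L),
                                end = c(10L, 20L, 40L)))
  expect_equal(nrow(m$intervals), 2L)  # adjacent intervals merge
  expect_equal(m$total_callable, 30L)
  p <- tempfile(fileext = ".bed")
  write_bed(m, p)
  expect_equal(callable_mask(read_bed(p))$intervals, m$intervals)
  expect_equal(mask_contains(m, c("chr1", "chr1", "chr2"), c(20L, 25L, 5L)),
               c(TRUE, FALSE, FALSE))
})
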