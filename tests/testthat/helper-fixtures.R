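# shared fixtures, built once per test session

.fixture_env <- new.env(parent = emptyenv())

# small genotype table built directly; geno rows are alt dosages
make_tab <- function(geno, pos = seq_len(nrow(geno)) * 10L, chrom = "chr1",
                     regions = NULL, depth = 50L, is_indel = FALSE,
                     is_multi = FALSE, ad = FALSE) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  ids <- colnames(geno) %||% paste0("s", seq_len(m))
  colnames(geno) <- ids
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep("A", n), alt = rep("T", n),
                      is_indel = rep_len(is_indel, n),
                      is_multiallelic = rep_len(is_multi, n),
                      stringsAsFactors = FALSE)
  samples <- data.frame(id = ids,
                        region = regions %||% rep("NA", m),
                        stringsAsFactors = FALSE)
  dp <- matrix(rep_len(depth, n * m), n, m)
  ad_ref <- ad_alt <- NULL
  if (ad) {
    ad_alt <- matrix(0L, n, m); ad_alt[geno == 1L] <- depth %/% 2L
    ad_alt[geno == 2L] <- depth
    ad_ref <- dp - ad_alt
  }
  genotype_table(sites, samples, geno, dp, ad_ref, ad_alt)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# full-extent mask over the table's chromosomes
full_mask <- function(len = 1000L, chroms = "chr1") {
  callable_mask(data.frame(chrom = chroms, start = 0L, end = len))
}

# the default synthetic radiation panel, generated once and cached
radsim_fixture <- function() {
  if (is.null(.fixture_env$radsim)) {
    dir <- file.path(tempdir(), "radpop_radsim")
    cfg <- radiation_sim_config(seed = 101L)
    sim <- simulate_radiation_vcf(cfg, dir = dir)
    tab <- load_vcf(sim$paths$vcf, sim$region_map)
    fl <- apply_site_filters(tab, filter_config(), read_bed(sim$paths$repeats_bed))
    .fixture_env$radsim <- list(cfg = cfg, sim = sim, raw = tab,
                                tab = fl$table, report = fl$report,
                                site_mask = fl$mask,
                                mask = callable_mask(read_bed(sim$paths$callable_bed)))
  }
  .fixture_env$radsim
}

# derived table constructed directly from a dosage matrix (ingroup only)
make_derived <- function(deriv, pos = seq_len(nrow(deriv)) * 10L,
                         chrom = "chr1", regions = NULL) {
  deriv <- as.matrix(deriv)
  ids <- colnames(deriv) %||% paste0("s", seq_len(ncol(deriv)))
  colnames(deriv) <- ids
  structure(list(sites = data.frame(chrom = rep_len(chrom, nrow(deriv)),
                                    pos = pos,
                                    ancestral_allele = "A",
                                    derived_allele = "T",
                                    stringsAsFactors = FALSE),
                 deriv = deriv,
                 samples = data.frame(id = ids,
                                      region = regions %||% rep("NA", length(ids)),
                                      stringsAsFactors = FALSE)),
            class = "derived_table")
}
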