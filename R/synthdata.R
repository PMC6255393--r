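#' Configuration for the synthetic resequencing panel
#'
#' Defines the study conditions the generator emulates: ten diploid ingroup
#' individuals in three geographic regions (4 North America, 2 Europe, 4
#' Asia) plus one outgroup; per-species heterozygosity drawn from a 0.2-0.35
#' percent band; seven chromosomes with doubled polymorphism on chromosome
#' "Chr_04"; directional gene flow between two designated Asian species
#' modelled by the trio coalescent; read-depth and allele-balance noise and
#' planted repeat intervals so the site filters have work to do.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param het_band heterozygosity band (percent) per-species targets are
#'   drawn from
#' @param multiplier_chrom,multiplier chromosome with elevated polymorphism
#'   and its diversity multiplier
#' @param trio (a, b, c) sample ids of the modelled Asian trio: `a` splits
#'   first, gene flow runs between `a` and `c`
#' @param gene_flow [gene_flow_model()] for the trio (desk-scale default
#'   N = 2000, m chosen so m N = 0.25)
#' @param theta trio mutation rate per lineage per N generations (controls
#'   pair-shared derived variants per window)
#' @param window_bp window granularity at which trio genealogies are drawn
#' @param clade_rate per-bp rate of clade-defining fixed derived variants
#' @param shared_rate per-bp rate of deep shared polymorphisms
#' @param divergence_rate per-bp rate of outgroup-fixed divergent sites
#'   (scaled far below real divergence; divergence level is not a target)
#' @param depth_mean,depth_size negative-binomial read-depth model
#' @param missing_rate per-cell probability of a missing genotype
#' @param unbalanced_het_rate fraction of het calls with skewed allele depths
#' @param ref_flip_rate fraction of sites whose VCF REF is the derived allele
#'   (outgroup homozygous ALT), exercising polarization
#' @param multiallelic_rate,indel_rate per-bp rates of filter-fodder records
#' @param repeat_fraction fraction of each chromosome masked as repeats
#' @param seed RNG seed
#' @return list of class `radiation_sim_config`
#' @export
radiation_sim_config <- function(
    chrom_lengths = stats::setNames(rep(500000L, 7), sprintf("Chr_%02d", 1:7)),
    het_band = c(0.2, 0.35),
    multiplier_chrom = "Chr_04", multiplier = 2.0,
    trio = c("oxy", "sib", "japon"),
    gene_flow = gene_flow_model(N = 2000, m = 0.25 / 2000, mode = "symmetric"),
    theta = 100, window_bp = 100000L,
    clade_rate = 4e-4, shared_rate = 3e-4, divergence_rate = 2e-3,
    depth_mean = 60, depth_size = 15, missing_rate = 0.002,
    unbalanced_het_rate = 0.03, ref_flip_rate = 0.1,
    multiallelic_rate = 5e-5, indel_rate = 5e-5,
    repeat_fraction = 0.05, seed = 1L) {
  if (multiplier <= 0) stop("multiplier must be positive")
  if (het_band[1] <= 0 || het_band[2] >= 100 || het_band[1] > het_band[2])
    stop("het_band must be an increasing band inside (0, 100)")
  samples <- data.frame(
    id = c("na1", "na2", "na3", "na4", "eu1", "eu2", trio, "as4", "out"),
    region = c(rep("NA", 4), rep("EU", 2), rep("AS", 4), "OUT"),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, chrom_lengths = chrom_lengths,
                 het_band = het_band, multiplier_chrom = multiplier_chrom,
                 multiplier = multiplier, trio = trio, gene_flow = gene_flow,
                 theta = theta, window_bp = window_bp,
                 clade_rate = clade_rate, shared_rate = shared_rate,
                 divergence_rate = divergence_rate,
                 depth_mean = depth_mean, depth_size = depth_size,
                 missing_rate = missing_rate,
                 unbalanced_het_rate = unbalanced_het_rate,
                 ref_flip_rate = ref_flip_rate,
                 multiallelic_rate = multiallelic_rate,
                 indel_rate = indel_rate,
                 repeat_fraction = repeat_fraction, seed = seed),
            class = "radiation_sim_config")
}

# clades planted on the species-tree backbone (defined on ingroup ids)
backbone_clades <- function(cfg) {
  tr <- cfg$trio
  list(NAm = c("na1", "na2", "na3", "na4"),
       NAm_a = c("na1", "na2"), NAm_b = c("na3", "na4"),
       EU = c("eu1", "eu2"),
       AS_nested = c(tr[2], tr[3], "as4"),
       Eurasia = c("eu1", "eu2", tr[2], tr[3], "as4"))
}

#' Simulate a multi-species resequencing panel as a VCF
#'
#' Writes a standards-compliant VCF plus companion files: a repeats BED, a
#' callable BED (chromosomes minus repeats), a sample-to-region map TSV and a
#' JSON truth record. Variant content per 100 kb window: per-sample
#' heterozygous sites at the species' target rate, clade-defining fixed
#' derived variants on the species-tree backbone, deep shared polymorphisms
#' (region-wide and genus-wide), outgroup-fixed divergent sites, and
#' pair-shared derived variants from a trio genealogy drawn per window from
#' [simulate_genealogies()] so incomplete lineage sorting and gene flow are
#' structurally correct. Depths are negative-binomial; heterozygous allele
#' depths are binomial with a configurable unbalanced fraction; multiallelic
#' and indel records and repeat intervals are planted for filter testing.
#'
#' @param cfg [radiation_sim_config()]
#' @param dir output directory (created if needed)
#' @return list: paths (vcf, repeats_bed, callable_bed, regions_tsv,
#'   truth_json), region_map, truth record (window topologies, per-species
#'   heterozygosity targets, model parameters)
#' @export
simulate_radiation_vcf <- function(cfg = radiation_sim_config(), dir = tempfile("radsim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  ids <- cfg$samples$id
  in_ids <- setdiff(ids, "out")
  ns <- length(ids)
  trio <- cfg$trio
  # per-species heterozygosity targets (percent)
  het_target <- stats::setNames(stats::runif(length(in_ids), cfg$het_band[1],
                                             cfg$het_band[2]), in_ids)
  clades <- backbone_clades(cfg)

  # windows across all chromosomes; one trio genealogy per window
  wins <- list(); k <- 0
  for (ch in names(cfg$chrom_lengths)) {
    st <- seq(0L, cfg$chrom_lengths[[ch]] - 1L, by = cfg$window_bp)
    for (s in st) {
      k <- k + 1
      wins[[k]] <- data.frame(chrom = ch, start = s,
                              end = min(s + cfg$window_bp, cfg$chrom_lengths[[ch]]),
                              stringsAsFactors = FALSE)
    }
  }
  wins <- do.call(rbind, wins)
  gsim <- simulate_genealogies(cfg$gene_flow, n_loci = nrow(wins),
                               theta = cfg$theta,
                               seed = sample.int(2^31 - 1, 1), detail = TRUE)
  wins$trio_pair <- gsim$loci$pair
  wins$trio_mutations <- gsim$loci$mutations

  # repeats: one interval per chromosome covering repeat_fraction of it
  rep_iv <- data.frame(chrom = names(cfg$chrom_lengths),
                       start = 0L,
                       end = as.integer(round(cfg$repeat_fraction *
                                                unname(cfg$chrom_lengths))))
  call_iv <- data.frame(chrom = rep_iv$chrom, start = rep_iv$end,
                        end = unname(cfg$chrom_lengths))

  site_rows <- list(); geno_rows <- list(); r <- 0
  for (w in seq_len(nrow(wins))) {
    ch <- wins$chrom[w]
    mult <- if (ch == cfg$multiplier_chrom) cfg$multiplier else 1
    L <- wins$end[w] - wins$start[w]
    patterns <- list()
    # 1. per-sample heterozygous sites
    for (s in in_ids) {
      n <- stats::rpois(1, mult * het_target[[s]] / 100 * L)
      if (n > 0) {
        m <- matrix(0L, n, ns, dimnames = list(NULL, ids)); m[, s] <- 1L
        patterns <- c(patterns, list(m))
      }
    }
    # 2. clade-defining fixed derived variants
    for (cl in clades) {
      n <- stats::rpois(1, mult * cfg$clade_rate * L)
      if (n > 0) {
        m <- matrix(0L, n, ns, dimnames = list(NULL, ids)); m[, cl] <- 2L
        patterns <- c(patterns, list(m))
      }
    }
    # 3. deep shared polymorphism: genus-wide and within-region
    n <- stats::rpois(1, mult * cfg$shared_rate * L)
    if (n > 0) {
      m <- matrix(0L, n, ns, dimnames = list(NULL, ids))
      m[, in_ids] <- ifelse(matrix(stats::runif(n * length(in_ids)) < 0.5, n),
                            sample(1:2, n * length(in_ids), replace = TRUE), 0L)
      keep <- rowSums(m) > 0
      if (any(keep)) patterns <- c(patterns, list(m[keep, , drop = FALSE]))
    }
    for (rg in c("NA", "EU", "AS")) {
      members <- cfg$samples$id[cfg$samples$region == rg]
      n <- stats::rpois(1, mult * cfg$shared_rate * L)
      if (n > 0) {
        m <- matrix(0L, n, ns, dimnames = list(NULL, ids))
        m[, members] <- ifelse(matrix(stats::runif(n * length(members)) < 0.8, n),
                               sample(1:2, n * length(members), replace = TRUE), 0L)
        keep <- rowSums(m) > 0
        if (any(keep)) patterns <- c(patterns, list(m[keep, , drop = FALSE]))
      }
    }
    # 4. divergence: outgroup fixed derived
    n <- stats::rpois(1, cfg$divergence_rate * L)
    if (n > 0) {
      m <- matrix(0L, n, ns, dimnames = list(NULL, ids)); m[, "out"] <- 2L
      patterns <- c(patterns, list(m))
    }
    # 5. trio pair-shared derived variants from the window genealogy
    nmut <- wins$trio_mutations[w]
    if (nmut > 0) {
      pairm <- switch(wins$trio_pair[w], trio[2:3], trio[c(1, 3)], trio[1:2])
      m <- matrix(0L, nmut, ns, dimnames = list(NULL, ids)); m[, pairm] <- 2L
      patterns <- c(patterns, list(m))
    }
    if (length(patterns) == 0) next
    G <- do.call(rbind, patterns)
    nsite <- nrow(G)
    pos <- sort(sample(seq.int(wins$start[w] + 1L, wins$end[w]), nsite))
    r <- r + 1
    site_rows[[r]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    geno_rows[[r]] <- G[sample.int(nsite), , drop = FALSE]  # shuffle pattern order
  }
  sites <- do.call(rbind, site_rows)
  D <- do.call(rbind, geno_rows)   # derived-allele dosage, all samples
  nsite <- nrow(sites)

  # allele labels; with ref_flip_rate the REF is the derived allele and the
  # outgroup is homozygous ALT
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, nsite, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
  flip <- stats::runif(nsite) < cfg$ref_flip_rate
  ref <- ifelse(flip, der, anc)
  alt <- ifelse(flip, anc, der)
  G <- D   # outgroup column is nonzero only at divergence sites
  G[flip, ] <- 2L - G[flip, , drop = FALSE]   # alt dosage when REF = derived

  # filter fodder: planted multiallelic and indel records
  extra_sites <- list(); extra_geno <- list(); e <- 0
  for (ch in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[ch]]
    nm <- stats::rpois(1, cfg$multiallelic_rate * L)
    ni <- stats::rpois(1, cfg$indel_rate * L)
    if (nm + ni == 0) next
    pos <- sample(seq_len(L), nm + ni)
    e <- e + 1
    extra_sites[[e]] <- data.frame(
      chrom = ch, pos = pos,
      ref = c(rep("A", nm), rep("AT", ni)),
      alt = c(rep("C,G", nm), rep("A", ni)),
      is_indel = c(rep(FALSE, nm), rep(TRUE, ni)),
      is_multiallelic = c(rep(TRUE, nm), rep(FALSE, ni)),
      stringsAsFactors = FALSE)
    extra_geno[[e]] <- matrix(sample(0:1, (nm + ni) * ns, replace = TRUE),
                              nm + ni, ns, dimnames = list(NULL, ids))
  }
  all_sites <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref,
                          alt = alt, is_indel = FALSE, is_multiallelic = FALSE,
                          stringsAsFactors = FALSE)
  if (e > 0) {
    all_sites <- rbind(all_sites, do.call(rbind, extra_sites))
    G <- rbind(G, do.call(rbind, extra_geno))
  }
  ord <- order(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[ord, , drop = FALSE]
  G <- G[ord, , drop = FALSE]
  dup <- duplicated(paste(all_sites$chrom, all_sites$pos))
  all_sites <- all_sites[!dup, , drop = FALSE]
  G <- G[!dup, , drop = FALSE]
  n <- nrow(all_sites)

  depth <- matrix(stats::rnbinom(n * ns, size = cfg$depth_size,
                                 mu = cfg$depth_mean), n, ns,
                  dimnames = list(NULL, ids))
  G[matrix(stats::runif(n * ns) < cfg$missing_rate, n, ns)] <- NA_integer_
  # allele depths: binomial split for hets, all-on-one-allele for homs
  p_alt <- matrix(0, n, ns)
  p_alt[!is.na(G) & G == 2L] <- 1
  het <- !is.na(G) & G == 1L
  p_het <- ifelse(stats::runif(sum(het)) < cfg$unbalanced_het_rate,
                  sample(c(0.12, 0.88), sum(het), replace = TRUE), 0.5)
  p_alt[het] <- p_het
  ad_alt <- matrix(stats::rbinom(n * ns, as.vector(depth), as.vector(p_alt)),
                   n, ns, dimnames = list(NULL, ids))
  ad_ref <- depth - ad_alt

  tab <- genotype_table(all_sites, cfg$samples, G, depth, ad_ref, ad_alt)
  paths <- list(vcf = file.path(dir, "panel.vcf"),
                repeats_bed = file.path(dir, "repeats.bed"),
                callable_bed = file.path(dir, "callable.bed"),
                regions_tsv = file.path(dir, "regions.tsv"),
                truth_json = file.path(dir, "truth.json"))
  write_vcf(tab, paths$vcf, contig_lengths = cfg$chrom_lengths)
  write_bed(rep_iv, paths$repeats_bed)
  write_bed(call_iv, paths$callable_bed)
  utils::write.table(cfg$samples, paths$regions_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(het_target_pct = as.list(het_target),
                multiplier_chrom = cfg$multiplier_chrom,
                multiplier = cfg$multiplier,
                trio = trio,
                gene_flow = unclass(cfg$gene_flow)[c("N", "m1", "m2", "t1", "t2", "tail", "mode")],
                d_sign = if (cfg$gene_flow$m1 > 0 || cfg$gene_flow$m2 > 0) 1 else 0,
                windows = wins, seed = cfg$seed)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = TRUE, digits = NA)
  region_map <- stats::setNames(cfg$samples$region, cfg$samples$id)
  list(paths = paths, region_map = region_map, truth = truth)
}

#' Simulate an F2 mapping panel from per-bin crossover intensities
#'
#' Per F2 individual and parent of origin one recombinant haplotype is walked
#' along each chromosome's bins: the count of crossovers in a bin is Poisson
#' with the bin's intensity and an odd count switches the carried
#' grandparent. Diagnostic reads are binomial around 0.5 for the carrying
#' haplotype and around a small error rate otherwise.
#'
#' @param intensities data.frame(chrom, start, end, lambda): expected
#'   crossovers per haploid genome per bin
#' @param n_f2 F2 individuals (two haploid genomes each)
#' @param mean_reads mean informative read count per bin
#' @param error_rate diagnostic-read rate for the non-carrying haplotype
#' @param seed RNG seed
#' @return list: counts (input for [assign_bin_genotypes()]), truth
#'   (per-bin switch counts over all haploids, n_haploid)
#' @export
simulate_f2_panel <- function(intensities, n_f2 = 324L, mean_reads = 100,
                              error_rate = 0.02, seed = 1L) {
  stopifnot(all(intensities$lambda >= 0))
  set.seed(seed)
  intensities <- intensities[order(intensities$chrom, intensities$start), ]
  nb <- nrow(intensities)
  truth_events <- numeric(nb)
  rows <- list(); r <- 0
  for (f2 in seq_len(n_f2)) for (par in c("p1", "p2")) {
    assign_gp <- integer(nb)
    for (ch in unique(intensities$chrom)) {
      bi <- which(intensities$chrom == ch)
      gp <- sample(1:2, 1)
      for (b in bi) {
        k <- stats::rpois(1, intensities$lambda[b])
        if (k %% 2 == 1) {
          gp <- 3L - gp
          truth_events[b] <- truth_events[b] + 1
        }
        assign_gp[b] <- gp
      }
    }
    possible <- stats::rpois(nb, mean_reads)
    p <- ifelse(assign_gp == 1L, 0.5, error_rate)
    observed <- stats::rbinom(nb, possible, p)
    r <- r + 1
    rows[[r]] <- data.frame(f2_id = sprintf("f2_%03d", f2), parent = par,
                            chrom = intensities$chrom,
                            start = intensities$start, end = intensities$end,
                            observed = observed, possible = possible,
                            stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, rows),
       truth = data.frame(intensities, events = truth_events,
                          n_haploid = 2L * n_f2))
}

#' Simulate per-bin genomic covariates with a chromosome-four contrast
#'
#' Generates recombination rate, exonic proportion, gene density, neutral
#' diversity and a D statistic per bin with specified linear structure and a
#' chromosome-four offset, for testing the regression and correlation
#' machinery.
#'
#' @param n_bins number of bins (spread over 7 chromosomes)
#' @param coef list of generating coefficients: exon = c(intercept, slope on
#'   recombination, chr4 offset), div = c(intercept, slope on gene density,
#'   chr4 offset), d = c(intercept, slope on gene density)
#' @param noise_sd named vector of Gaussian noise SDs for exon, div, d
#' @param seed RNG seed
#' @return list(bins = data.frame, truth = generating parameters)
#' @export
simulate_bin_covariates <- function(n_bins = 210L,
                                    coef = list(exon = c(0.30, -0.02, -0.10),
                                                div = c(0.45, -0.004, 0.30),
                                                d = c(0.30, -0.0025)),
                                    noise_sd = c(exon = 0.02, div = 0.03, d = 0.05),
                                    seed = 1L) {
  stopifnot(n_bins >= 10)
  set.seed(seed)
  chrom <- sprintf("Chr_%02d", rep(1:7, length.out = n_bins))
  is_chr4 <- chrom == "Chr_04"
  recomb <- stats::runif(n_bins, 0.5, 5)
  exon <- coef$exon[1] + coef$exon[2] * recomb + coef$exon[3] * is_chr4 +
    stats::rnorm(n_bins, 0, noise_sd[["exon"]])
  exon <- pmin(pmax(exon, 0.01), 0.99)
  gene_density <- exon * 1e4 / recomb   # exonic bp per cM in a 1 Mb bin
  div <- coef$div[1] + coef$div[2] * gene_density / 100 + coef$div[3] * is_chr4 +
    stats::rnorm(n_bins, 0, noise_sd[["div"]])
  dstat <- coef$d[1] + coef$d[2] * gene_density / 100 +
    stats::rnorm(n_bins, 0, noise_sd[["d"]])
  bins <- data.frame(chrom = chrom, is_chr4 = is_chr4,
                     recombination = recomb, prop_exonic = exon,
                     gene_density = gene_density, diversity = div,
                     d_stat = dstat, stringsAsFactors = FALSE)
  list(bins = bins, truth = list(coef = coef, noise_sd = as.list(noise_sd)))
}
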