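#' Assemble a pipeline configuration
#'
#' @param vcf multi-sample VCF path
#' @param region_map named vector sample -> region, or a two-column TSV path
#'   (id, region)
#' @param outgroup outgroup sample id
#' @param out_dir output directory for stage artifacts
#' @param repeats_bed optional repeats BED
#' @param callable_bed optional BED enumerating the callable genome for
#'   diversity denominators; defaults to the mask of surviving variant sites
#' @param filter [filter_config()]
#' @param window_bp,min_variants window-tree settings
#' @param dstat_roles list(h1, h2, h3) for the D-statistic stage
#' @param trio (a, b, c) for topology support and the coalescent fit
#' @param root_taxon taxon used to root window trees (default first trio
#'   member)
#' @param m_grid,N_grid coalescent fit grid
#' @param seed seed used by resampling stages
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(vcf, region_map, outgroup, out_dir,
                            repeats_bed = NULL, callable_bed = NULL,
                            filter = filter_config(),
                            window_bp = 100000L, min_variants = 100L,
                            dstat_roles = NULL, trio = NULL,
                            root_taxon = NULL,
                            m_grid = c(0, 5e-5, 1e-4, 2e-4),
                            N_grid = c(1000, 2000, 4000), seed = 1L) {
  if (is.character(region_map) && length(region_map) == 1) {
    rm_df <- utils::read.table(region_map, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    region_map <- stats::setNames(rm_df[[2]], rm_df[[1]])
  }
  if (!outgroup %in% names(region_map))
    stop("outgroup not present in region map: ", outgroup)
  structure(list(vcf = vcf, region_map = region_map, outgroup = outgroup,
                 out_dir = out_dir, repeats_bed = repeats_bed,
                 callable_bed = callable_bed, filter = filter,
                 window_bp = window_bp, min_variants = min_variants,
                 dstat_roles = dstat_roles, trio = trio,
                 root_taxon = root_taxon %||% trio[1],
                 m_grid = m_grid, N_grid = N_grid, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes filter, diversity, FST, polarize, sharing, D statistics, window
#' trees, subtree tests, topology support, and the coalescent grid fit,
#' writing one artifact per stage (TSV/Newick/BED) plus a JSON manifest with
#' versions, seed and per-stage row counts. Byte-identical outputs under a
#' fixed seed and configuration.
#'
#' @param cfg [pipeline_config()]
#' @return manifest (list), invisibly also written to
#'   `file.path(out_dir, "manifest.json")`
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "radpop",
                   version = as.character(utils::packageVersion("radpop")),
                   seed = cfg$seed, stages = list())
  t0 <- Sys.time()
  record <- function(name, rows, output) {
    manifest$stages[[name]] <<- list(status = "complete", rows = rows,
                                     output = output)
  }
  fail <- function(name, e) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  # 1 filter
  res <- run("filter", {
    tab <- load_vcf(cfg$vcf, cfg$region_map)
    repeats <- if (!is.null(cfg$repeats_bed)) read_bed(cfg$repeats_bed)
    fl <- apply_site_filters(tab, cfg$filter, repeats)
    write_filter_report(fl$report, file.path(cfg$out_dir, "filter_report.tsv"))
    write_bed(fl$mask, file.path(cfg$out_dir, "callable_sites.bed"))
    record("filter", nrow(fl$table$sites), "filter_report.tsv")
    fl
  })
  tab <- res$table
  mask <- if (!is.null(cfg$callable_bed))
    callable_mask(read_bed(cfg$callable_bed)) else res$mask

  # 2 diversity
  run("diversity", {
    dv <- diversity_table(tab, mask, pairs = "all")
    utils::write.table(dv, file.path(cfg$out_dir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("diversity", nrow(dv), "diversity.tsv")
  })

  # 3 fst between region pairs
  run("fst", {
    regs <- setdiff(unique(cfg$region_map), "OUT")
    rows <- list(); k <- 0
    for (i in seq_along(regs)) for (j in seq_along(regs)) if (i < j) {
      a <- names(cfg$region_map)[cfg$region_map == regs[i]]
      b <- names(cfg$region_map)[cfg$region_map == regs[j]]
      a <- intersect(a, tab$samples$id); b <- intersect(b, tab$samples$id)
      f <- hudson_fst(tab, a, b, mask)
      k <- k + 1
      rows[[k]] <- data.frame(region_a = regs[i], region_b = regs[j],
                              fst = f$fst, Hw = f$Hw, Hb = f$Hb)
    }
    fst <- do.call(rbind, rows)
    utils::write.table(fst, file.path(cfg$out_dir, "fst.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("fst", nrow(fst), "fst.tsv")
  })

  # 4 polarize
  der <- run("polarize", {
    if (!cfg$outgroup %in% tab$samples$id)
      stop("outgroup sample missing after filtering: ", cfg$outgroup)
    d <- polarize(tab, cfg$outgroup)
    out <- cbind(d$sites, as.data.frame(d$deriv))
    utils::write.table(out, file.path(cfg$out_dir, "derived.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("polarize", nrow(d$sites), "derived.tsv")
    d
  })

  # 5 sharing
  run("sharing", {
    sh <- sharing_classification(der)
    out <- data.frame(species = rownames(sh$proportions), sh$proportions,
                      check.names = FALSE)
    utils::write.table(out, file.path(cfg$out_dir, "sharing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("sharing", nrow(out), "sharing.tsv")
  })

  # 6 D statistics
  run("dstat", {
    roles <- cfg$dstat_roles %||%
      list(h1 = cfg$trio[2], h2 = cfg$trio[3], h3 = cfg$trio[1])
    r <- abba_baba(der, roles$h1, roles$h2, roles$h3)
    r <- block_significance(r, block_size = cfg$window_bp, seed = cfg$seed)
    out <- data.frame(h1 = r$h1, h2 = r$h2, h3 = r$h3, ABBA = r$ABBA,
                      BABA = r$BABA, D = r$D, SE = r$SE, Z = r$Z,
                      significant = r$significant)
    utils::write.table(out, file.path(cfg$out_dir, "dstat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("dstat", 1L, "dstat.tsv")
  })

  # 7 window trees
  ws <- run("window_trees", {
    w <- window_trees(tab, window_bp = cfg$window_bp,
                      min_variants = cfg$min_variants)
    write_window_trees(w, file.path(cfg$out_dir, "window_trees.nwk"))
    utils::write.table(w$windows, file.path(cfg$out_dir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("window_trees", length(w$trees), "window_trees.nwk")
    w
  })

  # 8 subtree tests
  run("subtree_tests", {
    st <- subtree_tests(ws, root_taxon = cfg$outgroup)
    utils::write.table(st$stage1, file.path(cfg$out_dir, "subtree_stage1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(st$stage2))
      utils::write.table(st$stage2, file.path(cfg$out_dir, "subtree_stage2.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    record("subtree_tests", nrow(st$stage1), "subtree_stage1.tsv")
  })

  # 9 topology support
  topo <- run("topology_support", {
    ts <- topology_support(der, cfg$trio)
    out <- data.frame(topology = names(ts$counts), count = ts$counts,
                      proportion = ts$proportions)
    utils::write.table(out, file.path(cfg$out_dir, "topology_support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("topology_support", 3L, "topology_support.tsv")
    ts
  })

  # 10 coalescent grid fit
  run("coal_fit", {
    fit <- fit_grid(topo$proportions, cfg$m_grid, cfg$N_grid)
    utils::write.table(fit$surface, file.path(cfg$out_dir, "coal_surface.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$best_fit <- fit$best
    record("coal_fit", nrow(fit$surface), "coal_surface.tsv")
  })

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
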