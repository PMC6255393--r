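#' Hamming distance matrix between samples
#'
#' Per pair, the proportion of jointly-called sites with differing genotype
#' codes (dosages 0/1/2 compared as symbols; any difference counts one).
#'
#' @param t [genotype_table()]
#' @param sites optional logical/integer site index
#' @return list(d = symmetric matrix, n = per-pair jointly-called site counts)
#' @export
hamming_distances <- function(t, sites = NULL) {
  G <- if (is.null(sites)) t$geno else t$geno[sites, , drop = FALSE]
  ids <- colnames(G)
  if (length(ids) < 3) stop("need >= 3 samples")
  m <- length(ids)
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  n <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ok <- !is.na(G[, i]) & !is.na(G[, j])
    nij <- sum(ok)
    if (nij == 0) stop("zero jointly-called sites for pair ", ids[i], "-", ids[j])
    d[i, j] <- d[j, i] <- sum(G[ok, i] != G[ok, j]) / nij
    n[i, j] <- n[j, i] <- nij
  }
  list(d = d, n = n)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken deterministically by scan order over the current taxon ordering
#' (input taxa first, merged nodes appended). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch, preserving
#' the pairwise distance between the joined nodes. Reconstructs any additive
#' matrix exactly.
#'
#' @param d symmetric distance matrix with row/col names (or the list
#'   returned by [hamming_distances()])
#' @return unrooted `phylo` tree
#' @export
neighbor_joining <- function(d) {
  if (is.list(d) && !is.null(d$d)) d <- d$d
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 taxa")
  node <- paste0(labs)  # newick fragment per active node
  D <- d
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    l <- clamp(li, lj)
    newick <- sprintf("(%s:%.12g,%s:%.12g)", node[i], l[1], node[j], l[2])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    node <- c(node[-c(i, j)], newick)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", node[1], la, node[2], lb,
                 node[3], lc)
  ape::read.tree(text = txt)
}

#' Neighbor-joining trees in non-overlapping genomic windows
#'
#' Tiles each chromosome with `window_bp` windows; windows with fewer than
#' `min_variants` variant positions, or with a sample pair lacking jointly
#' called sites, are skipped with a reason.
#'
#' @param t [genotype_table()]
#' @param window_bp window size (bp)
#' @param min_variants minimum variant positions per retained window
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last variant position per chromosome
#' @return list of class `window_tree_set`: `windows` data.frame (chrom,
#'   start, end, n_variants, status, reason), `trees` list of `phylo` for
#'   retained windows (names = window index)
#' @export
window_trees <- function(t, window_bp = 100000L, min_variants = 100L,
                         chrom_lengths = NULL) {
  chroms <- unique(t$sites$chrom)
  win <- list(); trees <- list(); k <- 0
  for (ch in chroms) {
    on_ch <- which(t$sites$chrom == ch)
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(t$sites$pos[on_ch])
    starts <- seq(0L, max(len - 1L, 0L), by = window_bp)
    for (st in starts) {
      en <- min(st + window_bp, len)
      idx <- on_ch[t$sites$pos[on_ch] > st & t$sites$pos[on_ch] <= en]
      k <- k + 1
      if (length(idx) < min_variants) {
        win[[k]] <- data.frame(chrom = ch, start = st, end = en,
                               n_variants = length(idx), status = "skipped",
                               reason = "too_few_variants", stringsAsFactors = FALSE)
        next
      }
      tre <- tryCatch(neighbor_joining(hamming_distances(t, idx)),
                      error = function(e) e)
      if (inherits(tre, "error")) {
        win[[k]] <- data.frame(chrom = ch, start = st, end = en,
                               n_variants = length(idx), status = "skipped",
                               reason = conditionMessage(tre), stringsAsFactors = FALSE)
      } else {
        win[[k]] <- data.frame(chrom = ch, start = st, end = en,
                               n_variants = length(idx), status = "retained",
                               reason = "", stringsAsFactors = FALSE)
        trees[[as.character(k)]] <- tre
      }
    }
  }
  structure(list(windows = do.call(rbind, win), trees = trees),
            class = "window_tree_set")
}

#' @export
print.window_tree_set <- function(x, ...) {
  cat("window_tree_set:", sum(x$windows$status == "retained"), "trees /",
      nrow(x$windows), "windows\n")
  invisible(x)
}

#' Write window trees as Newick, one per line
#' @param ws window_tree_set
#' @param path output file; window coordinates go in bracketed comments
#' @export
write_window_trees <- function(ws, path) {
  idx <- as.integer(names(ws$trees))
  lines <- vapply(seq_along(ws$trees), function(i) {
    w <- ws$windows[idx[i], ]
    paste0("[", w$chrom, ":", w$start, "-", w$end, "] ",
           ape::write.tree(ws$trees[[i]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# tip-label sets of all internal nodes of a rooted tree
clade_sets <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c0 <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c0]])
  }
  lapply(desc[(nt + 1):(nt + tree$Nnode)], sort)
}

#' Catalog rooted clades across window trees and test prevalence by chromosome
#'
#' Each retained window tree is rooted on `root_taxon`; every non-trivial
#' rooted clade (2 or more tips, not the full taxon set) is recorded. Stage 1
#' tests, per clade, equality of presence proportions across chromosomes
#' (chi-square test of equal proportions, no continuity correction),
#' Bonferroni-corrected for the number of unique clades. Stage 2, for clades
#' significant in stage 1, tests each chromosome's proportion against the
#' genome-wide proportion (one-sample proportion test with continuity
#' correction), Bonferroni-corrected for (significant clades x chromosomes).
#'
#' @param ws [window_trees()] result
#' @param root_taxon sample id used to root every tree
#' @param alpha significance level applied to corrected p-values
#' @return list(catalog = list(clades, presence matrix clades x windows,
#'   window_chrom), stage1 = data.frame, stage2 = data.frame)
#' @export
subtree_tests <- function(ws, root_taxon, alpha = 0.05) {
  idx <- as.integer(names(ws$trees))
  chrom <- ws$windows$chrom[idx]
  n_win <- length(ws$trees)
  clade_lists <- lapply(ws$trees, function(tr) {
    rt <- ape::root(tr, outgroup = root_taxon, resolve.root = TRUE)
    cl <- clade_sets(rt)
    keys <- vapply(cl, paste, character(1), collapse = "|")
    unique(keys[vapply(cl, length, integer(1)) < length(rt$tip.label)])
  })
  clades <- sort(unique(unlist(clade_lists)))
  presence <- vapply(clade_lists, function(k) clades %in% k,
                     logical(length(clades)))
  presence <- matrix(presence, nrow = length(clades),
                     dimnames = list(clades, NULL))
  res <- subtree_prevalence_test(presence, chrom, alpha = alpha)
  list(catalog = list(clades = clades, presence = presence,
                      window_chrom = chrom, n_windows = n_win),
       stage1 = res$stage1, stage2 = res$stage2)
}

#' Two-stage prevalence test on a clade presence matrix
#'
#' The testing core behind [subtree_tests()], usable directly on a logical
#' presence matrix (clades x windows) and a chromosome label per window.
#'
#' @param presence logical matrix clades x windows
#' @param chrom chromosome label per window
#' @param alpha significance level on Bonferroni-corrected p-values
#' @return list(stage1, stage2) data.frames
#' @export
subtree_prevalence_test <- function(presence, chrom, alpha = 0.05) {
  chroms <- sort(unique(chrom))
  n_by <- vapply(chroms, function(ch) sum(chrom == ch), integer(1))
  if (any(n_by == 0)) {
    warning("chromosomes with zero retained windows excluded")
    chroms <- chroms[n_by > 0]; n_by <- n_by[n_by > 0]
  }
  nc <- nrow(presence)
  s1 <- data.frame(clade = rownames(presence) %||% as.character(seq_len(nc)),
                   chisq = NA_real_, df = NA_integer_, p = NA_real_,
                   p_bonferroni = NA_real_, stringsAsFactors = FALSE)
  counts <- matrix(0L, nc, length(chroms), dimnames = list(NULL, chroms))
  for (ch in chroms) counts[, ch] <- rowSums(presence[, chrom == ch, drop = FALSE])
  for (i in seq_len(nc)) {
    x <- counts[i, ]
    props <- x / n_by
    if (length(unique(props)) == 1) {  # no variation (e.g. present everywhere)
      s1$chisq[i] <- 0; s1$df[i] <- length(chroms) - 1L; s1$p[i] <- 1
    } else {
      pt <- suppressWarnings(stats::prop.test(x, n_by, correct = FALSE))
      s1$chisq[i] <- unname(pt$statistic)
      s1$df[i] <- unname(pt$parameter)
      s1$p[i] <- pt$p.value
    }
  }
  s1$p_bonferroni <- pmin(1, s1$p * nc)
  sig <- which(!is.na(s1$p_bonferroni) & s1$p_bonferroni < alpha)
  s2 <- NULL
  if (length(sig) > 0) {
    n2 <- length(sig) * length(chroms)
    rows <- list(); k <- 0
    for (i in sig) {
      gprop <- sum(counts[i, ]) / sum(n_by)
      for (ch in chroms) {
        p2 <- if (gprop <= 0 || gprop >= 1) 1 else
          suppressWarnings(stats::prop.test(counts[i, ch], n_by[[ch]],
                                            p = gprop, correct = TRUE)$p.value)
        k <- k + 1
        rows[[k]] <- data.frame(clade = s1$clade[i], chrom = ch,
                                proportion = counts[i, ch] / n_by[[ch]],
                                genome_proportion = gprop, p = p2,
                                p_bonferroni = pmin(1, p2 * n2),
                                stringsAsFactors = FALSE)
      }
    }
    s2 <- do.call(rbind, rows)
  }
  list(stage1 = s1, stage2 = s2)
}
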