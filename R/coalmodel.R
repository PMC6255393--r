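#' Three-species coalescent model with gene flow
#'
#' Discrete-time model for the genealogy of one lineage from each of three
#' species a, b, c where species A (carrying lineage a) split first and
#' species B and C (lineages b, c) are sisters, with gene flow between A and
#' C from the present back to the first split. Time runs backwards in
#' generations; the haploid population size N is constant in every
#' population. Between t = 0 and t1 (in units of N generations) lineages a
#' and c migrate between populations A and C (A to C with probability `m1`
#' per generation, C to A with `m2`) and coalesce with probability 1/N per
#' generation when co-located. At t1 populations B and C merge; at t2 all
#' populations merge, after which a tail horizon of `tail` N generations is
#' simulated with all lineages co-located.
#'
#' @param N haploid population size (number of alleles), >= 2
#' @param m migration probability per generation; expanded to (m1, m2) by
#'   `mode`: symmetric m1 = m2 = m; unidirectional m1 = m, m2 = 0;
#'   asymmetric m1 = m, m2 = m/2 (i.e. m1 = 2 m2)
#' @param mode gene-flow mode
#' @param t1 first split time (units of N generations)
#' @param t2 second split time (default 2 t1)
#' @param tail post-t2 horizon (units of N generations)
#' @param m1,m2 set both rates explicitly (overrides `m`/`mode`)
#' @param phase2_generations number of generations the middle phase runs;
#'   default `round((t2 - t1) * N)`
#' @return object of class `gene_flow_model`
#' @export
gene_flow_model <- function(N, m = 0, mode = c("symmetric", "unidirectional",
                                               "asymmetric"),
                            t1 = 1, t2 = 2 * t1, tail = 1,
                            m1 = NULL, m2 = NULL, phase2_generations = NULL) {
  mode <- match.arg(mode)
  if (is.null(m1)) {
    m1 <- m
    m2 <- switch(mode, symmetric = m, unidirectional = 0, asymmetric = m / 2)
  }
  if (N < 2) stop("N must be >= 2")
  if (m1 < 0 || m1 >= 1 || m2 < 0 || m2 >= 1) stop("migration rates must be in [0, 1)")
  if (!(t2 > t1 && t1 > 0)) stop("need t2 > t1 > 0")
  if (tail < 0) stop("tail must be >= 0")
  structure(list(N = N, m1 = m1, m2 = m2, t1 = t1, t2 = t2, tail = tail,
                 mode = mode,
                 phase2_generations = phase2_generations %||% round((t2 - t1) * N)),
            class = "gene_flow_model")
}

#' @export
print.gene_flow_model <- function(x, ...) {
  cat(sprintf("gene_flow_model: N=%d m1=%g m2=%g (%s) t1=%g t2=%g tail=%g\n",
              x$N, x$m1, x$m2, x$mode, x$t1, x$t2, x$tail))
  invisible(x)
}

# per-generation coalescence: total probability k/N for k co-located pairs,
# split uniformly among the pairs (the discrete coalescent approximation;
# simultaneous-coalescence terms of order 1/N^2 are excluded)

#' Transition matrix of the migration-and-coalescence phase
#'
#' Five states track the locations of lineages a and c over populations A and
#' C, plus one absorbing a-c-coalesced state. Each generation both
#' uncoalesced lineages migrate (A to C with m1, C to A with m2), then a
#' co-located pair coalesces with probability 1/N. Lineage b is inert in this
#' phase.
#'
#' @param model [gene_flow_model()]
#' @return list of class `chain_spec`: phase, states, P (row-stochastic
#'   matrix), absorbing
#' @export
build_phase1_chain <- function(model) {
  N <- model$N; m1 <- model$m1; m2 <- model$m2
  states <- c("aA.cC", "aC.cC", "aA.cA", "aC.cA", "coal")
  # location codes: 0 = A, 1 = C; state order (la, lc)
  loc <- rbind(c(0, 1), c(1, 1), c(0, 0), c(1, 0))
  P <- matrix(0, 5, 5, dimnames = list(states, states))
  move <- function(l, to) if (l == 0) ifelse(to == 1, m1, 1 - m1) else
    ifelse(to == 0, m2, 1 - m2)
  for (s in 1:4) {
    for (la2 in 0:1) for (lc2 in 0:1) {
      p <- move(loc[s, 1], la2) * move(loc[s, 2], lc2)
      s2 <- which(loc[, 1] == la2 & loc[, 2] == lc2)
      if (la2 == lc2) {
        P[s, s2] <- P[s, s2] + p * (1 - 1 / N)
        P[s, 5] <- P[s, 5] + p / N
      } else P[s, s2] <- P[s, s2] + p
    }
  }
  P[5, 5] <- 1
  structure(list(phase = 1L, states = states, P = P, absorbing = "coal"),
            class = "chain_spec")
}

#' Transition matrix of the post-merge phase
#'
#' At t1 populations B and C merge into BC; migration stops, so lineage
#' locations are frozen over {A, BC}. Four transient states track which of
#' a, c sit in BC (b is always there); three absorbing states record the
#' first coalescing pair: (b,c) = T1 (species-tree concordant), (a,c) = T2,
#' (a,b) = T3. With k co-located pairs the per-generation coalescence
#' probability is k/N, split uniformly.
#'
#' @param model [gene_flow_model()]
#' @param phase1_end optional probability distribution over the five phase-1
#'   states; returned alongside as the mapped phase-2 start distribution
#'   (phase-1 coalesced mass enters absorbed T2).
#' @return `chain_spec`; when `phase1_end` is given, also `start`, the mapped
#'   7-state start distribution
#' @export
build_phase2_chain <- function(model, phase1_end = NULL) {
  N <- model$N
  states <- c("aA.cBC", "aBC.cBC", "aA.cA", "aBC.cA", "T1", "T2", "T3")
  P <- matrix(0, 7, 7, dimnames = list(states, states))
  P["aA.cBC", ] <- c(1 - 1 / N, 0, 0, 0, 1 / N, 0, 0)          # (b,c) only
  P["aBC.cBC", ] <- c(0, 1 - 3 / N, 0, 0, 1 / N, 1 / N, 1 / N) # all pairs
  P["aA.cA", ] <- c(0, 0, 1 - 1 / N, 0, 0, 1 / N, 0)           # (a,c) only
  P["aBC.cA", ] <- c(0, 0, 0, 1 - 1 / N, 0, 0, 1 / N)          # (a,b) only
  P["T1", "T1"] <- P["T2", "T2"] <- P["T3", "T3"] <- 1
  spec <- structure(list(phase = 2L, states = states, P = P,
                         absorbing = c("T1", "T2", "T3")),
                    class = "chain_spec")
  if (!is.null(phase1_end)) {
    if (abs(sum(phase1_end) - 1) > 1e-9 || any(phase1_end < -1e-12))
      stop("phase1_end is not a probability distribution")
    v <- stats::setNames(numeric(7), states)
    v[1:4] <- phase1_end[1:4]  # aA.cC->aA.cBC, aC.cC->aBC.cBC, aA.cA->aA.cA, aC.cA->aBC.cA
    v["T2"] <- phase1_end[5]   # a-c coalesced during phase 1
    spec$start <- v
  }
  spec
}

# tail phase: all uncoalesced lineages co-located
build_tail_chain <- function(model) {
  N <- model$N
  states <- c("open", "T1", "T2", "T3")
  P <- matrix(0, 4, 4, dimnames = list(states, states))
  P["open", ] <- c(1 - 3 / N, 1 / N, 1 / N, 1 / N)
  P["T1", "T1"] <- P["T2", "T2"] <- P["T3", "T3"] <- 1
  structure(list(phase = 3L, states = states, P = P,
                 absorbing = c("T1", "T2", "T3")), class = "chain_spec")
}

# P^k by repeated squaring
mat_pow <- function(P, k) {
  R <- diag(nrow(P))
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  R
}

#' Genealogy topology distribution under the chain model
#'
#' Iterates the phase-1 chain for `round(t1 N)` generations from state
#' (a in A, c in C), maps the result onto the phase-2 chain and iterates it
#' for `phase2_generations`, then pools all unabsorbed mass into a co-located
#' tail phase run for `round(tail N)` generations. Deterministic.
#'
#' @param model [gene_flow_model()]
#' @return list of class `topology_distribution`: pT1, pT2, pT3 (probability
#'   the first coalescence joins (b,c), (a,c), (a,b)) and pNone (no first
#'   coalescence within the horizon)
#' @export
topology_distribution <- function(model) {
  N <- model$N
  k1 <- round(model$t1 * N)
  k2 <- model$phase2_generations
  k3 <- round(model$tail * N)
  if (k1 < 1 || k2 < 1) stop("phase horizon of zero generations")
  c1 <- build_phase1_chain(model)
  v1 <- c(1, 0, 0, 0, 0) %*% mat_pow(c1$P, k1)
  c2 <- build_phase2_chain(model, phase1_end = as.vector(v1))
  v2 <- c2$start %*% mat_pow(c2$P, k2)
  v2 <- stats::setNames(as.vector(v2), c2$states)
  open <- sum(v2[1:4])
  res <- v2[c("T1", "T2", "T3")]
  if (k3 > 0 && open > 0) {
    c3 <- build_tail_chain(model)
    v3 <- c(open, 0, 0, 0) %*% mat_pow(c3$P, k3)
    v3 <- stats::setNames(as.vector(v3), c3$states)
    res <- res + v3[c("T1", "T2", "T3")]
    open <- v3["open"]
  }
  structure(list(pT1 = unname(res["T1"]), pT2 = unname(res["T2"]),
                 pT3 = unname(res["T3"]), pNone = unname(open)),
            class = "topology_distribution")
}

#' @export
print.topology_distribution <- function(x, ...) {
  cat(sprintf("pT1=%.4f pT2=%.4f pT3=%.4f pNone=%.4f\n",
              x$pT1, x$pT2, x$pT3, x$pNone))
  invisible(x)
}

#' Monte-Carlo genealogy simulation with mutation dropping
#'
#' Forward (event-level) stochastic simulation of the same two-phase process:
#' per-generation migration and coalescence draws during phase 1, geometric
#' waiting times in the migration-free later phases. For each locus the first
#' coalescing pair and its time are recorded; the genealogy is completed
#' (second coalescence after the remaining two lineages are co-located) and
#' mutations are dropped as Poisson counts on the internal branch, from which
#' the D statistic with roles H1 = b, H2 = c, H3 = a is computed - a mutation
#' on the internal branch above pair (a,c) yields an ABBA site, above (a,b) a
#' BABA site, above (b,c) a topology-concordant (uninformative) site.
#' Simulation is independent of the transition matrices used by
#' [topology_distribution()].
#'
#' @param model [gene_flow_model()]
#' @param n_loci number of independent loci
#' @param theta mutation rate per lineage per N generations
#' @param seed RNG seed (local)
#' @param detail also return per-locus first-coalescence pair, times,
#'   internal branch lengths and mutation counts
#' @return list: proportions (pT1, pT2, pT3, pNone within the horizon),
#'   counts, D, ABBA, BABA, n_loci; with `detail`, a `loci` data.frame
#' @export
simulate_genealogies <- function(model, n_loci, theta = 1, seed = NULL,
                                 detail = FALSE) {
  stopifnot(n_loci >= 1, theta > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  N <- model$N; m1 <- model$m1; m2 <- model$m2
  k1 <- round(model$t1 * N)
  k2 <- model$phase2_generations
  k3 <- round(model$tail * N)
  la <- integer(n_loci)        # 0 = A, 1 = C/BC
  lc <- rep(1L, n_loci)
  pair <- integer(n_loci)      # 0 open, 1 (b,c), 2 (a,c), 3 (a,b)
  tf <- rep(NA_real_, n_loci)  # first-coalescence generation
  loc1 <- rep(NA_integer_, n_loci)  # phase-1 coalescence location
  in_phase1 <- logical(n_loci)
  from_t3 <- logical(n_loci)   # phase-2 (a,c) event in population A
  active <- seq_len(n_loci)
  if (m1 > 0 || m2 > 0) {
    for (g in seq_len(k1)) {
      if (length(active) == 0) break
      na <- length(active)
      laa <- la[active]; lcc <- lc[active]
      u <- stats::runif(na)
      laa <- ifelse(laa == 0L, ifelse(u < m1, 1L, 0L), ifelse(u < m2, 0L, 1L))
      u <- stats::runif(na)
      lcc <- ifelse(lcc == 0L, ifelse(u < m1, 1L, 0L), ifelse(u < m2, 0L, 1L))
      la[active] <- laa; lc[active] <- lcc
      co <- which(laa == lcc)
      if (length(co) > 0) {
        hit <- co[stats::runif(length(co)) < 1 / N]
        if (length(hit) > 0) {
          loci <- active[hit]
          pair[loci] <- 2L; tf[loci] <- g; loc1[loci] <- la[loci]
          in_phase1[loci] <- TRUE
          active <- active[-hit]
        }
      }
    }
  }
  # phase 2: locations frozen; geometric waiting times per category
  if (length(active) > 0) {
    aBC <- la[active] == 1L; cBC <- lc[active] == 1L
    npairs <- ifelse(aBC & cBC, 3L, 1L)
    w <- stats::rgeom(length(active), npairs / N) + 1
    ev <- w <= k2
    if (any(ev)) {
      loci <- active[ev]
      tf[loci] <- k1 + w[ev]
      p <- integer(sum(ev))
      a2 <- aBC[ev]; c2 <- cBC[ev]
      both <- a2 & c2
      p[both] <- sample.int(3, sum(both), replace = TRUE)
      p[!a2 & c2] <- 1L
      p[!a2 & !c2] <- 2L
      p[a2 & !c2] <- 3L
      pair[loci] <- p
      from_t3[loci] <- !a2 & !c2
      active <- active[!ev]
    }
  }
  # tail: everything co-located; complete all remaining genealogies
  if (length(active) > 0) {
    w <- stats::rgeom(length(active), 3 / N) + 1
    tf[active] <- k1 + k2 + w
    pair[active] <- sample.int(3, length(active), replace = TRUE)
    active <- integer(0)
  }
  horizon <- k1 + k2 + k3
  none <- tf > horizon
  counts <- c(T1 = sum(pair == 1L & !none), T2 = sum(pair == 2L & !none),
              T3 = sum(pair == 3L & !none), none = sum(none))
  # second coalescence: remaining pair is (ancestor, third lineage)
  tmerge <- k1 + k2   # when population A joins BC
  t_coloc <- tf
  ph1 <- in_phase1
  # phase-1 (a,c) ancestor: in C -> co-located with b at t1; in A -> at tmerge
  t_coloc[ph1 & loc1 == 1L] <- pmax(tf[ph1 & loc1 == 1L], k1)
  t_coloc[ph1 & loc1 == 0L] <- tmerge
  late <- !ph1 & tf > k1
  # third lineage in A until tmerge: pair (b,c) with a in A; (a,b) with c in
  # A; (a,c) events in population A leave b separated until tmerge
  sep <- (late & pair == 1L & la == 0L & tf <= tmerge) |
    (late & pair == 3L & lc == 0L & tf <= tmerge) |
    (late & from_t3 & tf <= tmerge)
  t_coloc[sep] <- tmerge
  t_coloc <- pmax(t_coloc, tf)
  troot <- t_coloc + stats::rgeom(n_loci, 1 / N) + 1
  internal <- troot - tf
  muts <- stats::rpois(n_loci, theta / N * internal)
  A <- sum(muts[pair == 2L]); B <- sum(muts[pair == 3L])
  out <- list(proportions = counts / n_loci, counts = counts,
              ABBA = A, BABA = B,
              D = if (A + B > 0) (A - B) / (A + B) else NA_real_,
              n_loci = n_loci)
  if (detail)
    out$loci <- data.frame(pair = pair, t_first = tf, t_root = troot,
                           internal = internal, mutations = muts,
                           beyond_horizon = none)
  out
}

#' Fit migration rate and population size by grid search
#'
#' For every (m, N) grid point the chain topology distribution is computed,
#' normalized over resolved genealogies, and compared to observed topology
#' proportions by squared error. Ties break toward smaller m, then smaller N.
#'
#' @param observed numeric length-3 vector of observed (T1, T2, T3)
#'   proportions (e.g. `topology_support()$proportions`), summing to 1
#' @param m_grid,N_grid grid values
#' @param mode gene-flow mode passed to [gene_flow_model()]
#' @param t1,t2,tail model times
#' @return list(best = list(m, N, distance), surface = data.frame)
#' @export
fit_grid <- function(observed, m_grid, N_grid, mode = "symmetric",
                     t1 = 1, t2 = 2 * t1, tail = 1) {
  if (length(m_grid) == 0 || length(N_grid) == 0) stop("empty grid")
  if (abs(sum(observed) - 1) > 1e-6) stop("observed proportions must sum to 1")
  surface <- expand.grid(m = sort(m_grid), N = sort(N_grid))
  surface <- surface[order(surface$m, surface$N), , drop = FALSE]
  surface$distance <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(surface))) {
    mod <- gene_flow_model(N = surface$N[i], m = surface$m[i], mode = mode,
                           t1 = t1, t2 = t2, tail = tail)
    td <- topology_distribution(mod)
    p <- c(td$pT1, td$pT2, td$pT3) / (1 - td$pNone)
    surface$distance[i] <- sum((observed - p)^2)
    if (is.null(best) || surface$distance[i] < best$distance - 1e-15)
      best <- list(m = surface$m[i], N = surface$N[i],
                   distance = surface$distance[i])
  }
  list(best = best, surface = surface)
}
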