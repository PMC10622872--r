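#' Piecewise constant-rate decomposition of a gene tree
#'
#' Breaks each population's lifespan into time segments on which the
#' coalescent and migration rates are constant: boundaries fall at coalescent
#' events and migration events involving the population and at species
#' divergence times inside its lifespan.  The decomposition carries, per
#' segment, the duration, the number of lineages present and an indicator per
#' migration entry of whether the entry is active during the segment, plus
#' per-population coalescent counts and per-entry migration counts and
#' lineage-time exposures.  These are the sufficient statistics of the MSC-M
#' gene-tree density.
#'
#' @param gt an `mscm_gene_tree`.
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @param params an `mscm_params`.
#' @return an object of class `mscm_decomposition` with elements
#'   `segments` (data frame: `pop`, `t0`, `t1`, `duration`, `n`, and one
#'   logical indicator column per migration entry), `coal_counts` (per
#'   population), `mig_counts` and `mig_exposure` (per entry; the exposure is
#'   the sum of `n * duration` over active segments of the destination
#'   population).
#' @export
decompose <- function(gt, tree, mig, params) {
  tau <- params$tau
  ls <- pop_lifespans(tree, tau)
  root_time <- max(gt$time)
  nonroot <- setdiff(seq_len(gt$nnode), gt_root(gt))
  paths <- lapply(nonroot, lineage_path, gt = gt, tree = tree, tau = tau)
  allseg <- do.call(rbind, paths)
  w <- if (mig$n > 0L) migration_windows(tree, mig, tau) else NULL

  coal_counts <- integer(tree$npop)
  for (v in (gt$ntip + 1L):gt$nnode)
    coal_counts[gt$pop[v]] <- coal_counts[gt$pop[v]] + 1L

  mig_counts <- integer(mig$n)
  ev <- gt$events
  if (nrow(ev) > 0L) {
    for (i in seq_len(nrow(ev))) {
      v <- ev$node[i]; te <- ev$time[i]; s <- ev$to[i]
      path <- paths[[match(v, nonroot)]]
      f <- path$pop[path$t1 == te & path$t0 <= te][1L]
      e <- which(mig$src == s & mig$dst == f)
      if (length(e) != 1L)
        stop(sprintf("no migration entry matches event at %g on node %d",
                     te, v))
      mig_counts[e] <- mig_counts[e] + 1L
    }
  }

  seg_list <- list()
  for (j in seq_len(tree$npop)) {
    lo <- ls[j, "lo"]; up <- min(ls[j, "up"], root_time)
    if (up <= lo) next
    bounds <- c(lo, up, tau[tau > lo & tau < up])
    jsegs <- allseg[allseg$pop == j, , drop = FALSE]
    bounds <- c(bounds, jsegs$t0[jsegs$t0 > lo & jsegs$t0 < up],
                jsegs$t1[jsegs$t1 > lo & jsegs$t1 < up])
    bounds <- sort(unique(bounds))
    t0 <- bounds[-length(bounds)]; t1 <- bounds[-1L]
    mid <- (t0 + t1) / 2
    n <- vapply(mid, function(m) sum(jsegs$t0 <= m & jsegs$t1 > m), 0L)
    seg_list[[j]] <- data.frame(pop = j, t0 = t0, t1 = t1,
                                duration = t1 - t0, n = n)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  mig_exposure <- numeric(mig$n)
  if (mig$n > 0L) {
    for (e in seq_len(mig$n)) {
      act <- segments$pop == mig$dst[e] &
        segments$t0 >= w[e, "lo"] & segments$t1 <= w[e, "up"]
      segments[[paste0("I_", mig$from[e], "_", mig$to[e])]] <- act
      mig_exposure[e] <- sum(segments$n[act] * segments$duration[act])
    }
  }
  structure(list(segments = segments, coal_counts = coal_counts,
                 mig_counts = mig_counts, mig_exposure = mig_exposure),
            class = "mscm_decomposition")
}

#' Log density of a gene tree under the MSC-M model
#'
#' Exact density of a genealogy with migration history given the parameters:
#' a product over populations of variable-rate Poisson-process terms.  In
#' population j with locus heredity scalar h, a pair of lineages coalesces at
#' rate `2/(theta_j h)` and each lineage receives backward migration from
#' entry `s -> j` at rate `4 M_sj/(theta_j h)` while the entry is active, so
#' the log density is
#' `sum_j [ c_j log(2/(theta_j h)) - sum_k n_k(n_k-1) t_k/(theta_j h) ]
#'  + sum_{s,j} [ w_sj log(4 M_sj/(theta_j h)) - 4 M_sj B_sj/(theta_j h) ]`
#' with `c_j` coalescent counts, `w_sj` migration counts and `B_sj` active
#' lineage-time exposures.
#'
#' @inheritParams decompose
#' @param h heredity/ploidy scalar of the locus (1 autosomal, 3/4 X-linked,
#'   1/4 Y or mitochondrial).
#' @param heredity_scales_migration if `TRUE` (default) the heredity scalar
#'   rescales the per-lineage migration rate exactly as it does the coalescent
#'   rate (rate `4M/(theta h)`); set `FALSE` to apply it to coalescence only.
#' @return log density; `-Inf` if a migration event is present on an entry
#'   with rate 0.
#' @export
log_density_mscm <- function(gt, tree, mig, params, h = 1,
                             heredity_scales_migration = TRUE) {
  dec <- decompose(gt, tree, mig, params)
  theta <- params$theta
  seg <- dec$segments
  lp <- sum(dec$coal_counts * log(2 / (theta * h))) -
    sum(seg$n * (seg$n - 1L) * seg$duration / (theta[seg$pop] * h))
  if (mig$n > 0L) {
    hm <- if (heredity_scales_migration) h else 1
    thj <- theta[mig$dst]
    rate <- 4 * params$M / (thj * hm)
    cnt <- dec$mig_counts
    if (any(cnt > 0L & params$M == 0)) return(-Inf)
    lp <- lp + sum(ifelse(cnt > 0L, cnt * log(rate), 0)) -
      sum(rate * dec$mig_exposure)
  }
  lp
}

#' Closed-form density of the six-sequence worked genealogy
#'
#' Hand-transcribed log density for the canonical worked example on the
#' three-species tree `((A,B)S,C)R` with bidirectional B/C migration: two
#' sequences per species, coalescences at `t1 < t2 < t3 < t4 < t5` (a1-a2 in
#' A, c1-c2 in C, one pair in S, two in R) and one lineage (b2) migrating
#' B -> C at `s1` and back C -> B at `s2` (backward in time), with
#' `t1 < t2 < s1 < s2 < tau_S < t3 < tau_R < t4 < t5`.  Written independently
#' of [log_density_mscm()] as a term-by-term transcription of the five
#' population contributions, it serves as the analytic oracle for the general
#' implementation.
#'
#' @param tree the three-species tree with labels A, B, C, S, R.
#' @param params an `mscm_params` for that tree with migration entries
#'   B->C and C->B.
#' @param t numeric length 5, the coalescent times `t1..t5`.
#' @param s numeric length 2, the migration times `s1 < s2`.
#' @return log density.
#' @export
log_density_worked_example <- function(tree, params, t, s) {
  stopifnot(length(t) == 5L, length(s) == 2L)
  th <- function(lab) params$theta[pop_index(tree, lab)]
  tauS <- params$tau[pop_index(tree, "S")]
  tauR <- params$tau[pop_index(tree, "R")]
  ord <- c(t[1], t[2], s[1], s[2], tauS, t[3], tauR, t[4], t[5])
  if (any(diff(ord) <= 0))
    stop("times must satisfy t1<t2<s1<s2<tau_S<t3<tau_R<t4<t5")
  thA <- th("A"); thB <- th("B"); thC <- th("C"); thS <- th("S"); thR <- th("R")
  MBC <- params$M[1L]; MCB <- params$M[2L]
  termA <- log(2 / thA) - (2 / thA) * t[1]
  termB <- -(2 / thB) * (s[1] + tauS - s[2]) +
    log(4 * MCB / thB) -
    (4 * MCB / thB) * (2 * (s[1] + tauS - s[2]) + (s[2] - s[1]))
  termC <- log(2 / thC) - (2 / thC) * (t[2] + s[2] - s[1]) +
    log(4 * MBC / thC) -
    (4 * MBC / thC) * (2 * (t[2] + s[2] - s[1]) + (s[1] - t[2]) + (tauS - s[2]))
  termS <- log(2 / thS) - (6 / thS) * (t[3] - tauS) - (2 / thS) * (tauR - t[3])
  termR <- 2 * log(2 / thR) - (6 / thR) * (t[4] - tauR) - (2 / thR) * (t[5] - t[4])
  termA + termB + termC + termS + termR
}

#' Gene tree of the six-sequence worked genealogy
#'
#' Builds the `mscm_gene_tree` whose density
#' [log_density_worked_example()] transcribes: useful for tests and examples.
#'
#' @inheritParams log_density_worked_example
#' @return an `mscm_gene_tree` with tips a1,a2 (A), b1,b2 (B), c1,c2 (C).
#' @export
gene_tree_worked_example <- function(tree, params, t, s) {
  A <- pop_index(tree, "A"); B <- pop_index(tree, "B"); C <- pop_index(tree, "C")
  S <- pop_index(tree, "S"); R <- pop_index(tree, "R")
  ## tips 1..6: a1 a2 b1 b2 c1 c2; internal 7..11:
  ## 7 = (a1,a2) at t1 in A; 8 = (c1,c2) at t2 in C; 9 = (7,b1) at t3 in S;
  ## 10 = (9,8) at t4 in R; 11 = root (10,b2) at t5 in R.
  parent <- c(7L, 7L, 9L, 11L, 8L, 8L, 9L, 10L, 10L, 11L, NA)
  time <- c(0, 0, 0, 0, 0, 0, t[1], t[2], t[3], t[4], t[5])
  pop <- c(A, A, B, B, C, C, A, C, S, R, R)
  events <- data.frame(node = c(4L, 4L), time = s, to = c(C, B))
  gene_tree(tip_pop = c(A, A, B, B, C, C), parent = parent, time = time,
            pop = pop, events = events,
            labels = c("A^a1", "A^a2", "B^b1", "B^b2", "C^c1", "C^c2"))
}

#' Expected fraction of migrant lineages
#'
#' Probability that a lineage sampled in the destination population carries at
#' least one migration event before the divergence time `tau_d`, under
#' constant backward migration at per-lineage rate `4 M / theta`:
#' `phi0 = 1 - exp(-4 M tau_d / theta)`.  Used to translate a migration rate
#' into an effective introgression probability.
#'
#' @param M population migration rate (migrants per generation).
#' @param tau_d time depth over which migration can act.
#' @param theta mutation-scaled size of the destination population.
#' @return probability in `[0, 1)`.
#' @examples
#' phi0(0.1, 0.01, 0.01)  # 1 - exp(-0.4)
#' @export
phi0 <- function(M, tau_d, theta) {
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(M < 0) || any(tau_d < 0)) stop("M and tau_d must be >= 0")
  1 - exp(-4 * M * tau_d / theta)
}
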