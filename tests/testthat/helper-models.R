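# Shared model builders and independent oracles.

three_species_tree <- function() species_tree("((A, B)S, C)R;")

bc_migration <- function(tree) migration_spec(tree, c("B", "C"), c("C", "B"))

bc_params <- function(tree, mig, MBC = 0.2, MCB = 0.1) {
  param_set(tree, mig, tau = c(R = 0.02, S = 0.01),
            theta = c(A = 0.015, B = 0.025, C = 0.025, S = 0.015, R = 0.025),
            M = stats::setNames(c(MBC, MCB), c("B->C", "C->B")))
}

# valid random times for the six-sequence worked genealogy
# (t1 < t2 < s1 < s2 < tauS < t3 < tauR < t4 < t5)
worked_example_times <- function(tauS = 0.01, tauR = 0.02) {
  t12 <- sort(runif(2, 0, 0.6 * tauS))
  s12 <- sort(runif(2, t12[2], tauS * 0.99))
  t3 <- runif(1, tauS, tauR)
  t45 <- sort(tauR + rexp(2, 100))
  list(t = c(t12, t3, t45), s = s12)
}

# brute-force JC69 likelihood: explicit sum over internal-node states,
# no pattern compression, no pruning
brute_force_loglik <- function(locus, gt) {
  idx <- match(gt$labels, locus$labels)
  seqs <- locus$seqs[idx, , drop = FALSE]
  n <- gt$ntip
  internals <- (n + 1L):gt$nnode
  k <- length(internals)
  pmat <- lapply(seq_len(gt$nnode), function(v) {
    if (is.na(gt$parent[v])) NULL
    else jc69_transition(gt$time[gt$parent[v]] - gt$time[v])
  })
  states <- as.matrix(expand.grid(rep(list(1:4), k)))
  total <- 0
  for (site in seq_len(ncol(seqs))) {
    lik <- 0
    for (r in seq_len(nrow(states))) {
      assign_state <- integer(gt$nnode)
      assign_state[seq_len(n)] <- seqs[, site] + 1L
      assign_state[internals] <- states[r, ]
      p <- 0.25
      for (v in seq_len(gt$nnode)) {
        pa <- gt$parent[v]
        if (is.na(pa)) next
        p <- p * pmat[[v]][assign_state[pa], assign_state[v]]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# independent plain-MSC (no migration) gene-tree log density: iterates
# populations directly from the lineage counts at sorted event times, written
# without reusing decompose()
msc_only_logdens <- function(gt, tree, params, h = 1) {
  tau <- params$tau; theta <- params$theta
  ls <- pop_lifespans(tree, tau)
  root_time <- max(gt$time)
  lp <- 0
  for (j in seq_len(tree$npop)) {
    lo <- ls[j, "lo"]; up <- min(ls[j, "up"], root_time)
    if (up <= lo) next
    # entry time of each lineage into pop j: a lineage (edge above node v)
    # occupies j from max(time[v], lo) until min(time[parent], up) if its
    # (migration-free) path passes through j
    occ <- list()
    for (v in seq_len(gt$nnode)) {
      pa <- gt$parent[v]
      if (is.na(pa)) next
      p <- gt$pop[v]; t0 <- gt$time[v]
      while (TRUE) {
        t1 <- min(ls[p, "up"], gt$time[pa])
        if (p == j && t1 > t0) occ[[length(occ) + 1L]] <- c(t0, t1)
        if (t1 >= gt$time[pa]) break
        t0 <- t1; p <- tree$parent[p]
      }
    }
    if (length(occ) == 0L) next
    occ <- do.call(rbind, occ)
    times <- sort(unique(c(occ[, 1L], occ[, 2L])))
    for (i in seq_len(length(times) - 1L)) {
      mid <- (times[i] + times[i + 1L]) / 2
      nn <- sum(occ[, 1L] <= mid & occ[, 2L] > mid)
      lp <- lp - nn * (nn - 1L) * (times[i + 1L] - times[i]) / (theta[j] * h)
    }
    ncoal <- sum(gt$pop[(gt$ntip + 1L):gt$nnode] == j)
    lp <- lp + ncoal * log(2 / (theta[j] * h))
  }
  lp
}
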