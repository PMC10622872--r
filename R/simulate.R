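#' Sampling configuration for simulated datasets
#'
#' @param loci number of loci L.
#' @param seqs sequences per species per locus: a single integer (applied to
#'   every species) or a named integer vector by species label.
#' @param sites sites per sequence N.
#' @param heredity heredity/ploidy scalar(s): scalar or length-`loci` vector
#'   (1 autosomal, 3/4 X-linked, 1/4 Y or mitochondrial; any positive value
#'   accepted).
#' @return a list with class `mscm_config`.
#' @export
sample_config <- function(loci, seqs, sites, heredity = 1) {
  stopifnot(loci >= 0, sites >= 1, all(heredity > 0))
  if (length(heredity) == 1L) heredity <- rep(heredity, max(loci, 1L))
  structure(list(loci = as.integer(loci), seqs = seqs,
                 sites = as.integer(sites), heredity = heredity),
            class = "mscm_config")
}

seqs_per_species <- function(tree, seqs) {
  if (is.null(names(seqs))) {
    if (length(seqs) == 1L) seqs <- rep(seqs, tree$nsp)
    stopifnot(length(seqs) == tree$nsp)
    names(seqs) <- tree$labels[seq_len(tree$nsp)]
  }
  idx <- pop_index(tree, names(seqs))
  stopifnot(all(idx <= tree$nsp))
  out <- integer(tree$nsp)
  out[idx] <- as.integer(seqs)
  out
}

#' Simulate one gene tree under the MSC-M model
#'
#' Backward-in-time structured coalescent with migration: within each epoch
#' between species divergences the process is a constant-rate competing
#' Poisson process (pairwise coalescence at rate `2/(theta_j h)` in each
#' population, per-lineage migration at `4 M_sj/(theta_j h)` for each active
#' entry); at each divergence the clock is reset and the daughter populations'
#' lineages are relabelled to the ancestor, which is exact by memorylessness.
#'
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @param params an `mscm_params`.
#' @param seqs sequences per species (scalar or named by species label).
#' @param h heredity scalar of the locus.
#' @return an `mscm_gene_tree` (uses R's RNG; seed with [set.seed()]).
#' @export
sim_gene_tree <- function(tree, mig, params, seqs, h = 1) {
  ns <- seqs_per_species(tree, seqs)
  ntip <- sum(ns)
  if (ntip < 1L) stop("at least one sequence is required")
  tip_pop <- rep(seq_len(tree$nsp), ns)
  labels <- unlist(lapply(seq_len(tree$nsp), function(sp)
    if (ns[sp] > 0) paste0(tree$labels[sp], "^", seq_len(ns[sp])) else character()))
  nnode <- 2L * ntip - 1L
  parent <- rep(NA_integer_, nnode)
  time <- numeric(nnode)
  pop <- integer(nnode)
  pop[seq_len(ntip)] <- tip_pop
  ev_node <- integer(); ev_time <- numeric(); ev_to <- integer()

  theta <- params$theta; tau <- params$tau; M <- params$M
  w <- if (mig$n > 0L) migration_windows(tree, mig, tau) else NULL
  up <- pop_lifespans(tree, tau)[, "up"]
  epochs <- sort(unique(tau[tau > 0]))

  lin_id <- seq_len(ntip)        # node whose parent branch is open
  lin_pop <- tip_pop
  nxt <- ntip + 1L
  t <- 0
  if (ntip == 1L) {
    return(gene_tree(tip_pop, parent, time, pop,
                     events = NULL, labels = labels))
  }
  repeat {
    eend <- if (any(epochs > t)) min(epochs[epochs > t]) else Inf
    repeat {
      nj <- tabulate(lin_pop, nbins = tree$npop)
      rc <- nj * (nj - 1L) / (theta * h)
      if (mig$n > 0L) {
        act <- w[, "lo"] <= t & w[, "up"] >= eend
        rm <- ifelse(act, nj[mig$dst] * 4 * M / (theta[mig$dst] * h), 0)
      } else rm <- numeric()
      tot <- sum(rc) + sum(rm)
      if (tot == 0) { t <- eend; break }
      dt <- stats::rexp(1L, tot)
      if (t + dt >= eend) { t <- eend; break }
      t <- t + dt
      pick <- stats::runif(1L) * tot
      if (pick < sum(rc)) {
        j <- which(stats::runif(1L) * sum(rc) < cumsum(rc))[1L]
        members <- which(lin_pop == j)
        ij <- sample(members, 2L)
        parent[lin_id[ij]] <- nxt
        time[nxt] <- t; pop[nxt] <- j
        lin_id <- c(lin_id[-ij], nxt); lin_pop <- c(lin_pop[-ij], j)
        nxt <- nxt + 1L
        if (length(lin_id) == 1L) break
      } else {
        e <- which(stats::runif(1L) * sum(rm) < cumsum(rm))[1L]
        members <- which(lin_pop == mig$dst[e])
        i <- if (length(members) == 1L) members else sample(members, 1L)
        ev_node <- c(ev_node, lin_id[i]); ev_time <- c(ev_time, t)
        ev_to <- c(ev_to, mig$src[e])
        lin_pop[i] <- mig$src[e]
      }
    }
    if (length(lin_id) == 1L) break
    # promote lineages across the divergence(s) at t
    for (i in seq_along(lin_pop)) {
      while (up[lin_pop[i]] <= t) lin_pop[i] <- tree$parent[lin_pop[i]]
    }
    if (is.infinite(t)) stop("simulation failed to coalesce")  # unreachable
  }
  events <- if (length(ev_node) > 0L)
    data.frame(node = ev_node, time = ev_time, to = ev_to) else NULL
  gene_tree(tip_pop, parent, time, pop, events = events, labels = labels)
}

#' Simulate a JC69 sequence alignment down a gene tree
#'
#' Sites evolve independently under the Jukes-Cantor model from a uniform
#' root base; branch lengths are time differences (times are already in
#' expected mutations per site).  Migration events do not affect sequence
#' evolution: the mutation rate is population-independent.
#'
#' @param gt an `mscm_gene_tree`.
#' @param sites number of sites N.
#' @param h heredity scalar stored on the returned locus.
#' @return an `mscm_locus`: integer matrix `seqs` (tips x sites, codes 0..3
#'   for T,C,A,G), `labels`, `h`.
#' @export
sim_alignment <- function(gt, sites, h = 1) {
  nnode <- gt$nnode
  states <- matrix(0L, nnode, sites)
  ord <- order(gt$time, decreasing = TRUE)  # root first
  root <- gt_root(gt)
  states[root, ] <- sample.int(4L, sites, replace = TRUE) - 1L
  for (v in ord) {
    if (v == root) next
    bl <- gt$time[gt$parent[v]] - gt$time[v]
    ps <- 0.25 + 0.75 * exp(-4 * bl / 3)
    x <- states[gt$parent[v], ]
    mut <- stats::runif(sites) >= ps
    nm <- sum(mut)
    if (nm > 0L)
      x[mut] <- (x[mut] + sample.int(3L, nm, replace = TRUE)) %% 4L
    states[v, ] <- x
  }
  structure(list(seqs = states[seq_len(gt$ntip), , drop = FALSE],
                 labels = gt$labels, h = h),
            class = "mscm_locus")
}

#' @export
print.mscm_locus <- function(x, ...) {
  cat("MSC-M locus:", nrow(x$seqs), "sequences x", ncol(x$seqs),
      "sites, h =", x$h, "\n")
  invisible(x)
}

#' Simulate a multilocus dataset
#'
#' Simulates `config$loci` independent loci (free recombination between loci,
#' none within).  Each locus uses its own RNG stream derived from `seed`, so
#' locus k is bit-identical whether simulated alone or within a batch.
#'
#' @inheritParams sim_gene_tree
#' @param config an `mscm_config`.
#' @param seed integer base seed; locus k uses stream `locus_seed(seed, k)`.
#' @return list of `config$loci` elements, each `list(gene_tree, locus)`.
#' @export
sim_dataset <- function(tree, mig, params, config, seed) {
  lapply(seq_len(config$loci), function(k) {
    set.seed(locus_seed(seed, k))
    gt <- sim_gene_tree(tree, mig, params, config$seqs,
                        h = config$heredity[k])
    list(gene_tree = gt,
         locus = sim_alignment(gt, config$sites, h = config$heredity[k]))
  })
}

#' Per-locus RNG stream seed
#'
#' @param seed integer base seed.
#' @param k locus index.
#' @return integer seed below 2^31.
#' @export
locus_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Draw parameters from the prior and simulate a replicate dataset
#'
#' The generating step of Bayesian-simulation validation: parameters are
#' sampled from the prior and used to simulate a dataset, which is then
#' analysed under the same prior.
#'
#' @inheritParams sim_dataset
#' @param priors an `mscm_priors`.
#' @return `list(params, dataset)`.
#' @export
sim_bayesian_replicate <- function(priors, tree, mig, config, seed) {
  set.seed(locus_seed(seed, 0L))
  params <- sample_prior(priors, tree, mig)
  list(params = params,
       dataset = sim_dataset(tree, mig, params, config, seed))
}
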