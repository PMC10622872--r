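#' MCMC run settings
#'
#' @param iterations post-burn-in iterations (one sweep of every enabled move
#'   class per iteration).
#' @param burnin burn-in iterations (discarded; step sizes are auto-tuned
#'   during burn-in towards ~30% acceptance and frozen afterwards).
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param kernel divergence-time update variant: `"extended"` rescales
#'   migration times inside the rubber-band window, `"rejection"` leaves them
#'   untouched and abandons conflicting proposals (G-PhoCS style).
#' @param likelihood if `FALSE` the phylogenetic likelihood is held at 1 and
#'   the chain samples from the prior (times the gene-tree density), the
#'   standard validation mode.
#' @param beta power on the likelihood for power-posterior chains
#'   (thermodynamic integration); 1 for ordinary posterior sampling.
#' @param moves character vector of enabled move classes, a subset of
#'   `c("theta", "migrate", "migtime", "tau", "mixing", "spr")`.
#' @param spr_per_locus regraft proposals per locus per iteration.
#' @param steps named list of initial proposal step sizes
#'   (`theta`, `migrate`, `migtime`, `tau`, `mixing`).
#' @param tune,tune_interval auto-tune step sizes during burn-in.
#' @param check_every if positive, recompute all cached quantities from
#'   scratch every that many iterations and stop on any discrepancy (debug
#'   mode).
#' @param theta_in_mixing whether the mixing move also rescales population
#'   sizes (off by default).
#' @param prior_config latent-locus layout (an [sample_config()]) used when no
#'   sequence data are supplied.
#' @param broken_hastings testing hook: deliberately omits the multiplier
#'   Jacobian from the population-size update so that validation harnesses
#'   can demonstrate that they detect an incorrect Hastings ratio.  Never set
#'   this for real analyses.
#' @return list of class `mscm_control`.
#' @export
mcmc_control <- function(iterations = 2000L, burnin = 500L, thin = 1L,
                         kernel = c("extended", "rejection"),
                         likelihood = TRUE, beta = 1,
                         moves = c("theta", "migrate", "migtime", "tau",
                                   "mixing", "spr"),
                         spr_per_locus = 1L,
                         steps = list(), tune = TRUE, tune_interval = 50L,
                         check_every = 0L, theta_in_mixing = FALSE,
                         prior_config = sample_config(2, 2, 1),
                         broken_hastings = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(iterations >= 1, burnin >= 0, thin >= 1, beta >= 0, beta <= 1)
  bad <- setdiff(moves, c("theta", "migrate", "migtime", "tau", "mixing", "spr"))
  if (length(bad) > 0) stop("unknown move class: ", paste(bad, collapse = ", "))
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 kernel = kernel, likelihood = likelihood, beta = beta,
                 moves = moves, spr_per_locus = as.integer(spr_per_locus),
                 steps = steps, tune = tune,
                 tune_interval = as.integer(tune_interval),
                 check_every = as.integer(check_every),
                 theta_in_mixing = theta_in_mixing,
                 prior_config = prior_config,
                 broken_hastings = broken_hastings),
            class = "mscm_control")
}

default_steps <- function(priors) {
  tau_scale <- priors$tau["shape"] / priors$tau["rate"]
  list(theta = 0.5,
       migrate = 0.5 * priors$mig["shape"] / priors$mig["rate"],
       migtime = 0.5 * tau_scale,
       tau = 0.5 * tau_scale,
       mixing = 0.3)
}

init_params_prior_mean <- function(priors, tree, mig) {
  npop <- tree$npop
  theta <- rep(priors$theta["shape"] / priors$theta["rate"], npop)
  tau <- numeric(npop)
  tau[tree$root] <- priors$tau["shape"] / priors$tau["rate"]
  # walk down assigning each internal child 70% of its parent's age
  assign_down <- function(p) {
    for (ch in tree$children[p, ]) {
      if (!is.na(ch) && ch > tree$nsp) {
        tau[ch] <<- 0.7 * tau[p]
        assign_down(ch)
      }
    }
  }
  assign_down(tree$root)
  M <- rep(priors$mig["shape"] / priors$mig["rate"], mig$n)
  structure(list(tau = tau, theta = theta, M = M), class = "mscm_params")
}

species_of_labels <- function(tree, labels) {
  sp <- sub("\\^.*$", "", labels)
  pop_index(tree, sp)
}

engine_model <- function(tree, mig, params, priors) {
  list(nsp = tree$nsp, npop = tree$npop,
       pparent = ifelse(is.na(tree$parent), -1L, tree$parent - 1L),
       tau = params$tau, theta = params$theta,
       msrc = mig$src - 1L, mdst = mig$dst - 1L, M = params$M,
       prior = list(theta_shape = unname(priors$theta["shape"]),
                    theta_rate = unname(priors$theta["rate"]),
                    tau_shape = unname(priors$tau["shape"]),
                    tau_rate = unname(priors$tau["rate"]),
                    mig_shape = unname(priors$mig["shape"]),
                    mig_rate = unname(priors$mig["rate"])))
}

engine_locus <- function(gt, locus = NULL) {
  out <- list(ntip = gt$ntip,
              parent = ifelse(is.na(gt$parent), -1L, gt$parent - 1L),
              time = gt$time, pop = gt$pop - 1L,
              ev_node = gt$events$node - 1L, ev_time = gt$events$time,
              ev_to = gt$events$to - 1L, h = if (is.null(locus)) 1 else locus$h)
  if (!is.null(locus)) {
    idx <- match(gt$labels, locus$labels)
    sp <- site_patterns(structure(list(seqs = locus$seqs[idx, , drop = FALSE]),
                                  class = "mscm_locus"))
    out$pat <- sp$patterns
    out$cnt <- sp$counts
  }
  out
}

#' Run the MSC-M MCMC sampler
#'
#' Samples from `p(Theta, G | X)` proportional to
#' `p(Theta) p(G|Theta) p(X|G)^beta` over the parameters and the per-locus
#' gene trees with explicit migration histories.  Each iteration sweeps the
#' enabled move classes: multiplier updates of population sizes, sliding
#' windows on migration rates and migration-event times, rubber-band
#' divergence-time updates (extended or rejection variant, with
#' composite-space handling of migration rates whose activity flips),
#' regraft-by-simulation topology updates, and a global time-rescaling mixing
#' move.
#'
#' @param data list of `mscm_locus` alignments, or `NULL` to sample with the
#'   likelihood fixed at 1 (prior validation mode; latent loci follow
#'   `control$prior_config`).
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @param priors an `mscm_priors`.
#' @param control an [mcmc_control()].
#' @param seed integer seed governing initialisation and the sampler.
#' @param start optional `mscm_params` starting point; defaults to the prior
#'   means.
#' @return an object of class `mscm_trace`: `samples` matrix (one named
#'   column per parameter plus `lnG`, `lnL`, `nMig`, `meanRootAge`), `moves`
#'   acceptance summary, final engine state, and run metadata.
#' @export
run_mcmc <- function(data, tree, mig, priors, control = mcmc_control(),
                     seed = 1L, start = NULL) {
  stopifnot(inherits(control, "mscm_control"))
  params0 <- if (is.null(start)) init_params_prior_mean(priors, tree, mig)
             else start
  bad <- validate_model(tree, mig, params0)
  bad <- bad[!grepl("inactive", bad)]  # inactive entries allowed in sampler
  if (length(bad) > 0) stop("invalid starting model: ", bad[[1L]])

  use_lik <- control$likelihood && !is.null(data)
  if (is.null(data)) {
    cfg <- control$prior_config
    nloc <- cfg$loci
    loci_in <- vector("list", nloc)
    seqs <- cfg$seqs
  } else {
    nloc <- length(data)
    loci_in <- data
  }
  eng_loci <- vector("list", nloc)
  for (k in seq_len(nloc)) {
    set.seed(locus_seed(seed, k))
    if (is.null(data)) {
      gt <- sim_gene_tree(tree, mig, params0, seqs,
                          h = cfg$heredity[min(k, length(cfg$heredity))])
      eng_loci[[k]] <- engine_locus(gt, NULL)
    } else {
      lc <- loci_in[[k]]
      spk <- species_of_labels(tree, lc$labels)
      ns <- tabulate(spk, nbins = tree$nsp)
      gt <- sim_gene_tree(tree, mig, params0, stats::setNames(ns, tree$labels[seq_len(tree$nsp)]),
                          h = lc$h)
      # align tip labels with the data (grouped by species, data order within)
      gt$labels <- unlist(lapply(seq_len(tree$nsp),
                                 function(s) lc$labels[spk == s]))
      eng_loci[[k]] <- engine_locus(gt, if (use_lik) lc else NULL)
    }
  }
  steps <- utils::modifyList(default_steps(priors), control$steps)
  settings <- list(
    iterations = control$iterations, burnin = control$burnin,
    thin = control$thin, seed = as.double(seed %% 2147483647 + 1),
    beta = control$beta, use_likelihood = use_lik,
    kernel = if (control$kernel == "extended") 0L else 1L,
    broken_hastings = control$broken_hastings,
    theta_in_mixing = control$theta_in_mixing,
    spr_per_locus = control$spr_per_locus,
    steps = steps[c("theta", "migrate", "migtime", "tau", "mixing")],
    tune = control$tune, tune_interval = control$tune_interval,
    check_every = control$check_every,
    enable = c("theta", "migrate", "migtime", "tau", "mixing", "spr") %in%
      control$moves)
  res <- cpp_run_mcmc(engine_model(tree, mig, params0, priors), eng_loci,
                      settings)
  internals <- (tree$nsp + 1L):tree$npop
  cn <- c(paste0("tau_", tree$labels[internals]),
          paste0("theta_", tree$labels),
          mig_labels(mig), "lnG", "lnL", "nMig", "meanRootAge")
  colnames(res$trace) <- cn
  structure(list(samples = res$trace, moves = res$moves,
                 final = res[c("tau", "theta", "M", "final_loci",
                               "final_logG", "final_logl", "cache_delta")],
                 tree = tree, mig = mig, priors = priors,
                 control = control, seed = seed),
            class = "mscm_trace")
}

#' @export
print.mscm_trace <- function(x, ...) {
  cat("MSC-M MCMC trace:", nrow(x$samples), "samples,",
      ncol(x$samples) - 4L, "parameters\n")
  print(summary(x))
  invisible(x)
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing `ceiling(prob * n)` of the sorted samples.
#'
#' @param x numeric samples.
#' @param prob target mass.
#' @return numeric `c(lower, upper)`.
#' @examples
#' hpd_interval(stats::runif(1e4))  # close to width 0.95
#' @export
hpd_interval <- function(x, prob = 0.95) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples")
  xs <- sort(x)
  m <- min(n, ceiling(prob * n))
  k <- n - m + 1L
  widths <- xs[m:n] - xs[seq_len(k)]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

#' Posterior summary of a trace
#'
#' @param object an `mscm_trace`.
#' @param prob HPD mass.
#' @param ... unused.
#' @return data frame with posterior mean and HPD bounds per parameter.
#' @export
summary.mscm_trace <- function(object, prob = 0.95, ...) {
  summarize_trace(object, prob = prob)
}

#' @rdname summary.mscm_trace
#' @param trace an `mscm_trace` or a samples matrix.
#' @export
summarize_trace <- function(trace, prob = 0.95) {
  m <- if (inherits(trace, "mscm_trace")) trace$samples else trace
  keep <- setdiff(colnames(m), c("lnG", "lnL", "nMig", "meanRootAge"))
  out <- data.frame(parameter = keep,
                    mean = colMeans(m[, keep, drop = FALSE]))
  hp <- t(vapply(keep, function(p) {
    x <- m[, p]
    if (max(x) == min(x)) c(x[1L], x[1L]) else hpd_interval(x, prob)
  }, numeric(2)))
  out$hpd_lower <- hp[, 1L]
  out$hpd_upper <- hp[, 2L]
  rownames(out) <- NULL
  out
}
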