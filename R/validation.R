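#' Prior-sampling check of the MCMC kernels
#'
#' Runs the sampler with the likelihood fixed at 1, in which case every
#' parameter marginal must equal its prior (the gene-tree density integrates
#' to one over genealogies).  Each marginal is compared with its prior by a
#' Kolmogorov-Smirnov test: exact one-sample tests against the gamma prior
#' for population sizes, migration rates and the root age, and a two-sample
#' test against fresh prior draws for non-root divergence times (whose
#' marginal is not a standard distribution).  MCMC output is autocorrelated,
#' so the KS statistics are computed on a thinned subsample.
#'
#' @param tree,mig,priors model specification.
#' @param control an [mcmc_control()]; `likelihood` is forced off.
#' @param seed integer seed.
#' @param ks_thin thinning interval applied before the KS test.
#' @return object of class `mscm_calibration`: data frame `tests`
#'   (parameter, statistic, p-value), the trace, and the thinning used.
#' @export
prior_sampling_check <- function(tree, mig, priors,
                                 control = mcmc_control(likelihood = FALSE),
                                 seed = 1L, ks_thin = 20L) {
  control$likelihood <- FALSE
  tr <- run_mcmc(NULL, tree, mig, priors, control = control, seed = seed)
  m <- tr$samples
  sub <- m[seq(1L, nrow(m), by = ks_thin), , drop = FALSE]
  internals <- (tree$nsp + 1L):tree$npop
  rootcol <- paste0("tau_", tree$labels[tree$root])
  rows <- list()
  for (cn in colnames(m)) {
    if (cn %in% c("lnG", "lnL", "nMig", "meanRootAge")) next
    x <- sub[, cn]
    if (startsWith(cn, "theta_")) {
      kt <- ks_quiet(x, stats::pgamma, priors$theta["shape"],
                           priors$theta["rate"])
    } else if (startsWith(cn, "M_")) {
      kt <- ks_quiet(x, stats::pgamma, priors$mig["shape"],
                           priors$mig["rate"])
    } else if (cn == rootcol) {
      kt <- ks_quiet(x, stats::pgamma, priors$tau["shape"],
                           priors$tau["rate"])
    } else {
      # two-sample reference well above the subsample size so the reference's
      # own Monte-Carlo noise contributes little to the KS statistic
      nref <- max(8000L, 8L * length(x))
      ref <- vapply(seq_len(nref),
                    function(i) sample_prior(priors, tree, mig)$tau,
                    numeric(tree$npop))
      lab <- sub("^tau_", "", cn)
      kt <- ks_quiet(x, ref[pop_index(tree, lab), ])
    }
    rows[[cn]] <- data.frame(parameter = cn,
                             statistic = unname(kt$statistic),
                             p_value = kt$p.value)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  structure(list(tests = tests, trace = tr, ks_thin = ks_thin),
            class = "mscm_calibration")
}

#' @export
print.mscm_calibration <- function(x, ...) {
  if (!is.null(x$tests)) {
    cat("Prior-sampling check (KS against priors):\n")
    print(x$tests, row.names = FALSE)
  }
  if (!is.null(x$coverage)) {
    cat("95% HPD coverage over", x$n_rep, "replicates:\n")
    print(x$coverage, row.names = FALSE)
  }
  invisible(x)
}

#' Bayesian-simulation calibration
#'
#' Draws parameters from the prior, simulates a replicate dataset for each
#' draw, analyses each dataset under the same prior, and reports per-parameter
#' coverage of the 95% HPD interval (which should be ~95%) together with a
#' KS distance between the pooled posterior samples and the prior (the
#' average posterior over replicates should match the prior).  This
#' end-to-end test exercises both the simulator and the inference machinery.
#'
#' @param tree,mig,priors model specification.
#' @param config an [sample_config()] giving the per-replicate data size.
#' @param n_rep number of replicates (>= 2).
#' @param control an [mcmc_control()] for the per-replicate analyses.
#' @param seed integer seed.
#' @param prob HPD mass (default 0.95).
#' @return object of class `mscm_calibration` with elements `coverage`
#'   (per-parameter covered counts, proportion and pooled-vs-prior KS
#'   distance) and `n_rep`.
#' @export
bayesian_calibration <- function(tree, mig, priors, config, n_rep,
                                 control = mcmc_control(), seed = 1L,
                                 prob = 0.95) {
  stopifnot(n_rep >= 2)
  cover <- NULL
  pooled <- list()
  truth_cols <- NULL
  for (r in seq_len(n_rep)) {
    rep_seed <- locus_seed(seed, 50000L + r)
    rep <- sim_bayesian_replicate(priors, tree, mig, config, rep_seed)
    tr <- run_mcmc(lapply(rep$dataset, `[[`, "locus"), tree, mig, priors,
                   control = control, seed = rep_seed)
    sm <- summarize_trace(tr, prob = prob)
    truth <- c(rep$params$tau[(tree$nsp + 1L):tree$npop],
               rep$params$theta, rep$params$M)
    if (is.null(cover)) {
      truth_cols <- sm$parameter
      cover <- stats::setNames(numeric(length(truth)), truth_cols)
    }
    cover <- cover + as.numeric(truth >= sm$hpd_lower & truth <= sm$hpd_upper)
    keep <- seq(1L, nrow(tr$samples), by = max(1L, nrow(tr$samples) %/% 200L))
    pooled[[r]] <- tr$samples[keep, truth_cols, drop = FALSE]
  }
  pool <- do.call(rbind, pooled)
  ksd <- vapply(truth_cols, function(cn) {
    x <- pool[, cn]
    if (startsWith(cn, "theta_"))
      return(unname(ks_quiet(x, stats::pgamma, priors$theta["shape"],
                                   priors$theta["rate"])$statistic))
    if (startsWith(cn, "M_"))
      return(unname(ks_quiet(x, stats::pgamma, priors$mig["shape"],
                                   priors$mig["rate"])$statistic))
    if (cn == paste0("tau_", tree$labels[tree$root]))
      return(unname(ks_quiet(x, stats::pgamma, priors$tau["shape"],
                                   priors$tau["rate"])$statistic))
    ref <- vapply(seq_len(2000L),
                  function(i) sample_prior(priors, tree, mig)$tau,
                  numeric(tree$npop))
    unname(ks_quiet(x, ref[pop_index(tree, sub("^tau_", "", cn)), ])$statistic)
  }, numeric(1))
  coverage <- data.frame(parameter = truth_cols,
                         covered = as.integer(cover),
                         proportion = as.numeric(cover) / n_rep,
                         pooled_prior_ks = ksd)
  rownames(coverage) <- NULL
  structure(list(coverage = coverage, n_rep = n_rep, prob = prob),
            class = "mscm_calibration")
}

# MCMC output repeats values after rejected proposals, so exact-tie warnings
# from ks.test are expected and carry no information here.
ks_quiet <- function(...) suppressWarnings(stats::ks.test(...))
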