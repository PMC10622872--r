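#' Gauss-Legendre power schedule for thermodynamic integration
#'
#' Legendre nodes and weights on (-1, 1), computed by the Golub-Welsch
#' eigenvalue method and mapped linearly to the unit interval, give the
#' quadrature points `beta_k` in (0, 1) and weights summing to 1 used to
#' integrate the expected log-likelihood along the power-posterior path.
#'
#' @param K number of quadrature points, `K >= 1`.
#' @return object of class `mscm_schedule`: data frame with `beta`
#'   (increasing) and `weight`.
#' @examples
#' schedule(1)  # beta = 0.5, weight 1
#' schedule(2)  # beta = 0.5 +/- 1/(2*sqrt(3))
#' @export
schedule <- function(K) {
  if (K < 1) stop("K must be >= 1")
  if (K == 1L) {
    nodes <- 0
    weights <- 2
  } else {
    k <- seq_len(K - 1L)
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, K, K)
    J[cbind(k, k + 1L)] <- b
    J[cbind(k + 1L, k)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    nodes <- e$values[ord]
    weights <- 2 * e$vectors[1L, ord]^2
  }
  out <- data.frame(beta = (nodes + 1) / 2, weight = weights / 2)
  class(out) <- c("mscm_schedule", "data.frame")
  out
}

#' Marginal likelihood by thermodynamic integration
#'
#' Runs one power-posterior chain per quadrature point, targeting
#' `p(Theta) p(G|Theta) p(X|G)^beta_k`, records the mean log-likelihood under
#' each, and returns the Gauss-Legendre quadrature estimate of
#' `log p(X) = integral_0^1 E_beta[log p(X|G)] d beta`, with a Monte-Carlo
#' standard error from autocorrelation-adjusted batch means.
#'
#' @param data list of `mscm_locus` alignments.
#' @param tree,mig,priors model specification as in [run_mcmc()].
#' @param sched an [schedule()]; default 8 points.
#' @param control an [mcmc_control()] used for every power chain (its `beta`
#'   is overridden).
#' @param seed integer; chain k uses an independent derived stream.
#' @param start optional starting `mscm_params`, forwarded to [run_mcmc()].
#' @return list of class `mscm_logml`: `logml`, `se`, and the per-point
#'   table.
#' @export
log_marginal <- function(data, tree, mig, priors, sched = schedule(8),
                         control = mcmc_control(), seed = 1L, start = NULL) {
  stopifnot(inherits(sched, "mscm_schedule"))
  rows <- lapply(seq_len(nrow(sched)), function(k) {
    ctl <- control
    ctl$beta <- sched$beta[k]
    tr <- run_mcmc(data, tree, mig, priors, control = ctl,
                   seed = locus_seed(seed, 1000L + k), start = start)
    ll <- tr$samples[, "lnL"]
    nb <- max(4L, floor(sqrt(length(ll))))
    bm <- tapply(ll, ceiling(seq_along(ll) / (length(ll) / nb)), mean)
    data.frame(beta = sched$beta[k], mean_loglik = mean(ll),
               se = stats::sd(bm) / sqrt(length(bm)))
  })
  tab <- do.call(rbind, rows)
  est <- sum(sched$weight * tab$mean_loglik)
  se <- sqrt(sum((sched$weight * tab$se)^2))
  structure(list(logml = est, se = se, points = tab), class = "mscm_logml")
}

#' @export
print.mscm_logml <- function(x, ...) {
  cat("log marginal likelihood:", format(x$logml, digits = 6),
      "+/-", format(x$se, digits = 3), "\n")
  invisible(x)
}

#' Bayes factor from two log marginal likelihoods
#'
#' `log B = log p(X|model a) - log p(X|model b)`; the conventional
#' significance threshold for a gene-flow test is `|log B| > 4.6`
#' (B > 100 or B < 0.01).
#'
#' @param logml_a,logml_b numbers or `mscm_logml` objects.
#' @return list with `logB`, `significant`, and (when available) `se`.
#' @examples
#' bayes_factor(4.7, 0)$significant
#' @export
bayes_factor <- function(logml_a, logml_b) {
  va <- if (inherits(logml_a, "mscm_logml")) logml_a$logml else logml_a
  vb <- if (inherits(logml_b, "mscm_logml")) logml_b$logml else logml_b
  if (!is.finite(va) || !is.finite(vb)) stop("log marginals must be finite")
  se <- sqrt(sum(c(if (inherits(logml_a, "mscm_logml")) logml_a$se^2 else 0,
                   if (inherits(logml_b, "mscm_logml")) logml_b$se^2 else 0)))
  lb <- va - vb
  list(logB = lb, significant = abs(lb) > 4.6, se = se)
}
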