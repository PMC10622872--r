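#' Prior specification for MSC-M parameters
#'
#' Gamma priors, parameterised by (shape, rate) with mean shape/rate, are
#' placed on every population size theta, on the root divergence time, and on
#' every migration rate.  Conditional on the root age the remaining internal
#' node ages are uniform over the order-constrained region (each child younger
#' than its parent), a proper prior whose density is proportional to
#' `1/tau_root^k` with `k` the number of non-root internal nodes; the
#' shape-dependent constant is omitted as it cancels in all Metropolis
#' ratios.
#'
#' @param theta_shape,theta_rate gamma shape and rate for population sizes.
#' @param tau_shape,tau_rate gamma shape and rate for the root age.
#' @param mig_shape,mig_rate gamma shape and rate for migration rates.
#' @return object of class `mscm_priors`.
#' @examples
#' prior_spec(theta_shape = 4, theta_rate = 200,
#'            tau_shape = 4, tau_rate = 200, mig_shape = 2, mig_rate = 10)
#' @export
prior_spec <- function(theta_shape, theta_rate, tau_shape, tau_rate,
                       mig_shape = 2, mig_rate = 10) {
  vals <- c(theta_shape, theta_rate, tau_shape, tau_rate, mig_shape, mig_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior shapes and rates must be positive")
  structure(list(theta = c(shape = theta_shape, rate = theta_rate),
                 tau = c(shape = tau_shape, rate = tau_rate),
                 mig = c(shape = mig_shape, rate = mig_rate)),
            class = "mscm_priors")
}

#' Draw a parameter set from the prior
#'
#' Population sizes and migration rates are independent gamma draws; the root
#' age is gamma and the remaining internal node ages are sampled uniformly on
#' the order-constrained region given the root age (by rejection, which is
#' cheap on the small species trees this model targets).
#'
#' @param priors an `mscm_priors`.
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @return an `mscm_params` draw.
#' @export
sample_prior <- function(priors, tree, mig) {
  npop <- tree$npop; nsp <- tree$nsp
  theta <- stats::rgamma(npop, priors$theta["shape"], priors$theta["rate"])
  tau <- numeric(npop)
  root <- tree$root
  tau[root] <- stats::rgamma(1L, priors$tau["shape"], priors$tau["rate"])
  inner <- setdiff((nsp + 1L):npop, root)
  if (length(inner) > 0L) {
    repeat {
      tau[inner] <- stats::runif(length(inner), 0, tau[root])
      ok <- TRUE
      for (p in inner) {
        pa <- tree$parent[p]
        if (tau[p] >= tau[pa]) { ok <- FALSE; break }
      }
      if (ok) break
    }
  }
  M <- if (mig$n > 0L)
    stats::rgamma(mig$n, priors$mig["shape"], priors$mig["rate"])
  else numeric()
  structure(list(tau = tau, theta = theta, M = M), class = "mscm_params")
}

#' Log prior density of a parameter set
#'
#' Sums the gamma log densities of all population sizes, the root age and all
#' migration rates (active or not: inactive rates are retained as
#' pseudo-parameters with pseudo-prior equal to the prior, so their terms are
#' always included), plus the uniform order-statistics term `-k*log(tau_root)`
#' for the non-root ages.  Returns `-Inf` for non-positive parameters or
#' violated age ordering.
#'
#' @inheritParams sample_prior
#' @param params an `mscm_params`.
#' @return finite log density, or `-Inf` outside the support.
#' @export
log_prior <- function(params, priors, tree, mig) {
  nsp <- tree$nsp; npop <- tree$npop; root <- tree$root
  theta <- params$theta; tau <- params$tau; M <- params$M
  if (any(theta <= 0) || tau[root] <= 0) return(-Inf)
  inner <- setdiff((nsp + 1L):npop, root)
  for (p in inner) {
    if (tau[p] <= 0 || tau[p] >= tau[tree$parent[p]]) return(-Inf)
  }
  if (mig$n > 0L && any(M <= 0)) return(-Inf)
  lp <- sum(stats::dgamma(theta, priors$theta["shape"], priors$theta["rate"],
                          log = TRUE)) +
    stats::dgamma(tau[root], priors$tau["shape"], priors$tau["rate"],
                  log = TRUE) -
    length(inner) * log(tau[root])
  if (mig$n > 0L)
    lp <- lp + sum(stats::dgamma(M, priors$mig["shape"], priors$mig["rate"],
                                 log = TRUE))
  lp
}
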