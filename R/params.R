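#' Parameter set for an MSC-M model
#'
#' Bundles divergence times, population sizes and migration rates,
#' Theta = (tau, theta, M).  `tau` and `theta` are measured in expected
#' mutations per site, `M` in expected migrants per generation.
#'
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @param tau named numeric of divergence times for the internal populations
#'   (names are population labels); tips are fixed at 0.
#' @param theta named numeric of population sizes, one per population (tips
#'   and ancestors).
#' @param M numeric of migration rates, one per migration entry, in the order
#'   of `mig`; recycled if scalar.  May be a named vector with names
#'   `"from->to"`.
#' @return an object of class `mscm_params`: list with full-length `tau`
#'   (zeros at tips), `theta` and `M` vectors aligned to the tree/migration
#'   indexing.
#' @export
param_set <- function(tree, mig, tau, theta, M = numeric(mig$n)) {
  full_tau <- numeric(tree$npop)
  idx <- pop_index(tree, names(tau))
  if (any(idx <= tree$nsp)) stop("tau can only be supplied for internal nodes")
  full_tau[idx] <- as.numeric(tau)
  if (any(full_tau[(tree$nsp + 1L):tree$npop] == 0))
    warning("some internal nodes have tau = 0")
  full_theta <- numeric(tree$npop)
  full_theta[pop_index(tree, names(theta))] <- as.numeric(theta)
  if (length(M) == 1L && mig$n > 1L) M <- rep(M, mig$n)
  if (!is.null(names(M)) && mig$n > 0L) {
    want <- paste0(mig$from, "->", mig$to)
    if (!setequal(names(M), want)) stop("names of M do not match entries")
    M <- M[want]
  }
  if (length(M) != mig$n) stop("M must have one rate per migration entry")
  structure(list(tau = full_tau, theta = full_theta, M = as.numeric(M)),
            class = "mscm_params")
}

#' @export
print.mscm_params <- function(x, ...) {
  cat("MSC-M parameters: ", sum(x$tau > 0), " tau, ", length(x$theta),
      " theta, ", length(x$M), " M\n", sep = "")
  invisible(x)
}

#' Validate an MSC-M model configuration
#'
#' Checks the structural invariants of a (species tree, migration spec,
#' parameters) triple and returns diagnostics rather than raising errors:
#' positive population sizes, positive internal divergence times, child
#' times below parent times, non-negative migration rates, and every
#' migration entry active (its two populations contemporaries) under the
#' supplied divergence times.
#'
#' @inheritParams param_set
#' @param params an `mscm_params`.
#' @return character vector of human-readable violations; empty if the model
#'   is valid.
#' @export
validate_model <- function(tree, mig, params) {
  out <- character()
  tau <- params$tau; theta <- params$theta
  for (p in seq_len(tree$npop)) {
    if (theta[p] <= 0)
      out <- c(out, sprintf("theta[%s] must be > 0", tree$labels[p]))
    if (p > tree$nsp && tau[p] <= 0)
      out <- c(out, sprintf("tau[%s] must be > 0", tree$labels[p]))
    if (!is.na(tree$parent[p]) && p > tree$nsp &&
        tau[p] >= tau[tree$parent[p]])
      out <- c(out, sprintf("tau[%s] must be < tau[%s] (child below parent)",
                            tree$labels[p], tree$labels[tree$parent[p]]))
  }
  if (mig$n > 0L) {
    if (any(params$M < 0))
      out <- c(out, "migration rates must be >= 0")
    w <- migration_windows(tree, mig, tau)
    inactive <- w[, "lo"] >= w[, "up"]
    for (e in which(inactive))
      out <- c(out, sprintf(
        "migration entry %s->%s is inactive: populations are never contemporaries",
        mig$from[e], mig$to[e]))
  }
  out
}
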