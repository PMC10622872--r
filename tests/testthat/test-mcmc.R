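test_that("hpd_interval matches an exhaustive window search", {
  brute <- function(x, prob) {
    xs <- sort(x); n <- length(x); m <- ceiling(prob * n)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - m + 1L)) {
      w <- xs[i + m - 1L] - xs[i]
      if (w < best[1]) best <- c(w, xs[i], xs[i + m - 1L])
    }
    best[2:3]
  }
  set.seed(1)
  for (i in 1:5) {
    x <- rgamma(1000, 2, 3)
    expect_equal(hpd_interval(x, 0.9), brute(x, 0.9), ignore_attr = TRUE)
    expect_equal(hpd_interval(x, 0.95), brute(x, 0.95), ignore_attr = TRUE)
  }
  u <- runif(2e4)
  hp <- hpd_interval(u, 0.95)
  expect_equal(hp[2] - hp[1], 0.95, tolerance = 0.02)
  expect_equal(diff(hpd_interval(rep(1, 10))), 0)
})

test_that("a fixed seed reproduces the trace bit for bit", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  ctl <- mcmc_control(iterations = 300, burnin = 100, likelihood = FALSE,
                      prior_config = sample_config(2, 2, 1))
  t1 <- run_mcmc(NULL, tr, mig, pr, control = ctl, seed = 4)
  t2 <- run_mcmc(NULL, tr, mig, pr, control = ctl, seed = 4)
  expect_identical(t1$samples, t2$samples)
  t3 <- run_mcmc(NULL, tr, mig, pr, control = ctl, seed = 5)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("caches equal fresh recomputation throughout a checked run", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  pp <- bc_params(tr, mig)
  set.seed(9)
  ds <- sim_dataset(tr, mig, pp, sample_config(4, 2, 100), seed = 17)
  ctl <- mcmc_control(iterations = 400, burnin = 100, check_every = 50)
  tt <- run_mcmc(lapply(ds, `[[`, "locus"), tr, mig, pr, control = ctl,
                 seed = 2)
  expect_lt(tt$final$cache_delta, 1e-8)
  # final per-locus engine densities equal the R density of the final state
  for (k in seq_along(tt$final$final_loci)) {
    fl <- tt$final$final_loci[[k]]
    gt <- gene_tree(tip_pop = fl$pop[seq_len(fl$ntip)] + 1L,
                    parent = ifelse(fl$parent < 0, NA_integer_, fl$parent + 1L),
                    time = fl$time, pop = fl$pop + 1L,
                    events = if (length(fl$ev_node) > 0)
                      data.frame(node = fl$ev_node + 1L, time = fl$ev_time,
                                 to = fl$ev_to + 1L) else NULL)
    pfin <- structure(list(tau = tt$final$tau, theta = tt$final$theta,
                           M = tt$final$M), class = "mscm_params")
    expect_identical(check_gene_tree(gt, tr, mig, pfin), character(0))
    expect_equal(tt$final$final_logG[k],
                 log_density_mscm(gt, tr, mig, pfin), tolerance = 1e-7)
  }
})

test_that("prior-only chains recover every parameter's prior", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  ctl <- mcmc_control(iterations = 40000, burnin = 2000, likelihood = FALSE,
                      prior_config = sample_config(2, 2, 1))
  chk <- prior_sampling_check(tr, mig, pr, control = ctl, seed = 11,
                              ks_thin = 25)
  expect_true(all(chk$tests$p_value > 0.01))
  # acceptance rates are sane and the proposal statistics track attempts
  mv <- chk$trace$moves
  expect_true(all(mv$accepts <= mv$attempts))
  rates <- mv$accepts[mv$attempts > 0] / mv$attempts[mv$attempts > 0]
  expect_true(all(rates >= 0 & rates <= 1))
})

test_that("rejection and extended kernels agree on the posterior", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  ds <- sim_dataset(tr, mig, pp, sample_config(8, 2, 200), seed = 33)
  loci <- lapply(ds, `[[`, "locus")
  ctl1 <- mcmc_control(iterations = 4000, burnin = 1000, kernel = "extended")
  ctl2 <- mcmc_control(iterations = 4000, burnin = 1000, kernel = "rejection")
  s1 <- summary(run_mcmc(loci, tr, mig, pr, control = ctl1, seed = 3))
  s2 <- summary(run_mcmc(loci, tr, mig, pr, control = ctl2, seed = 4))
  # posterior means agree within a generous Monte-Carlo margin
  for (i in seq_len(nrow(s1))) {
    scale <- max(abs(s1$mean[i]), abs(s2$mean[i]))
    expect_lt(abs(s1$mean[i] - s2$mean[i]) / scale, 0.35)
  }
})

test_that("two-sequence single-population conditional is exponential", {
  # with the likelihood off and only regraft moves, the pair coalescent time
  # is resampled from its full conditional Exp(2/theta)
  tr <- species_tree("(A, B)R;")
  m0 <- migration_spec(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  start <- param_set(tr, m0, tau = c(R = 1e-12),
                     theta = c(A = 0.02, B = 0.02, R = 0.02))
  ctl <- mcmc_control(iterations = 20000, burnin = 200, likelihood = FALSE,
                      moves = "spr", prior_config = sample_config(1, 1, 1))
  tt <- run_mcmc(NULL, tr, m0, pr, control = ctl, seed = 8, start = start)
  ages <- tt$samples[, "meanRootAge"]
  sub <- ages[seq(1, length(ages), by = 10)]
  ks <- suppressWarnings(stats::ks.test(sub, stats::pexp, 2 / 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("composite-space moves cross the activity boundary correctly", {
  # S -> C on the balanced four-species tree exists only while tau_S < tau_T;
  # under the prior the chain must spend half its time on each side
  tr4 <- species_tree("((A, B)S, (C, D)T)R;")
  mig4 <- migration_spec(tr4, "S", "C")
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  ctl <- mcmc_control(iterations = 60000, burnin = 3000, likelihood = FALSE,
                      prior_config = sample_config(2, 1, 1))
  tt <- run_mcmc(NULL, tr4, mig4, pr, control = ctl, seed = 21)
  m <- tt$samples
  below <- m[, "tau_S"] < m[, "tau_T"]
  expect_gt(sum(diff(below) != 0), 100)  # many boundary crossings
  expect_lt(abs(mean(below) - 0.5), 0.03)
  # the retained rate keeps its prior marginal throughout
  sub <- seq(1, nrow(m), by = 30)
  ks <- suppressWarnings(stats::ks.test(m[sub, "M_S_C"], stats::pgamma, 2, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("trace summaries expose posterior means and HPD bounds", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  ctl <- mcmc_control(iterations = 500, burnin = 100, likelihood = FALSE,
                      prior_config = sample_config(1, 2, 1))
  tt <- run_mcmc(NULL, tr, mig, pr, control = ctl, seed = 1)
  sm <- summary(tt)
  expect_setequal(sm$parameter,
                  c("tau_R", "tau_S", paste0("theta_", tr$labels),
                    "M_B_C", "M_C_B"))
  expect_true(all(sm$hpd_lower <= sm$mean & sm$mean <= sm$hpd_upper))
  expect_equal(unname(unlist(hpd_interval(tt$samples[, "tau_R"]))),
               unlist(sm[sm$parameter == "tau_R", c("hpd_lower", "hpd_upper")]),
               ignore_attr = TRUE)
})
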