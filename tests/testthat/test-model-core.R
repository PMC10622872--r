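test_that("a complete three-species migration model validates cleanly", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  expect_identical(validate_model(tr, mig, pp), character(0))
})

test_that("violations are reported as diagnostics, one per broken rule", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  pp$theta[1] <- 0
  out <- validate_model(tr, mig, pp)
  expect_length(out, 1L)
  expect_match(out, "theta\\[A\\]")

  # S -> C on the balanced four-species tree: the entry dies when tau_S >= tau_T
  tr4 <- species_tree("((A, B)S, (C, D)T)R;")
  mig4 <- migration_spec(tr4, "S", "C")
  bad <- param_set(tr4, mig4, tau = c(R = 0.03, S = 0.02, T = 0.01),
                   theta = stats::setNames(rep(0.01, 7), tr4$labels), M = 0.1)
  out <- validate_model(tr4, mig4, bad)
  expect_length(out, 1L)
  expect_match(out, "inactive")
})

test_that("migration entries are active exactly when lifespans overlap", {
  tr4 <- species_tree("((A, B)S, (C, D)T)R;")
  mig4 <- migration_spec(tr4, "S", "C")
  tauA <- c(0, 0, 0, 0, 0.03, 0.01, 0.02)  # tau_S < tau_T
  tauB <- c(0, 0, 0, 0, 0.03, 0.02, 0.01)  # tau_S > tau_T
  expect_equal(nrow(active_migration_entries(tr4, mig4, tauA)), 1L)
  expect_equal(nrow(active_migration_entries(tr4, mig4, tauB)), 0L)
  # two extant tips are always contemporaries near the present
  migT <- migration_spec(tr4, "A", "C")
  expect_equal(nrow(active_migration_entries(tr4, migT, tauA)), 1L)
  expect_equal(nrow(active_migration_entries(tr4, migT, tauB)), 1L)
})

test_that("shrinking a population's lifespan never activates its entries", {
  tr4 <- species_tree("((A, B)S, (C, D)T)R;")
  mig4 <- migration_spec(tr4, c("S", "S", "C"), c("C", "D", "S"))
  set.seed(42)
  for (i in 1:100) {
    tauR <- runif(1, 0.01, 0.05)
    tauS <- runif(1, 0, tauR); tauT <- runif(1, 0, tauR)
    tau1 <- c(0, 0, 0, 0, tauR, tauS, tauT)
    tau2 <- tau1
    tau2[6] <- runif(1, tauS, tauR)  # raising tau_S shrinks S's lifespan
    a1 <- paste(active_migration_entries(tr4, mig4, tau1)$from,
                active_migration_entries(tr4, mig4, tau1)$to)
    a2 <- paste(active_migration_entries(tr4, mig4, tau2)$from,
                active_migration_entries(tr4, mig4, tau2)$to)
    expect_true(all(a2 %in% a1))
  }
})

test_that("prior sampling and evaluation are consistent", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  set.seed(1)
  draws <- replicate(2e4, sample_prior(pr, tr, mig)$theta[1])
  expect_equal(mean(draws), 0.02, tolerance = 0.02)
  set.seed(7); a <- sample_prior(pr, tr, mig)
  set.seed(7); b <- sample_prior(pr, tr, mig)
  expect_identical(a, b)
  # log_prior finite on every draw; -Inf outside the support
  set.seed(2)
  for (i in 1:200) {
    p <- sample_prior(pr, tr, mig)
    expect_true(is.finite(log_prior(p, pr, tr, mig)))
  }
  p$M[1] <- -0.1
  expect_identical(log_prior(p, pr, tr, mig), -Inf)
})

test_that("log_prior equals the sum of independent marginal terms", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(3, 150, 5, 100, 2, 10)
  set.seed(3)
  p <- sample_prior(pr, tr, mig)
  manual <- sum(dgamma(p$theta, 3, 150, log = TRUE)) +
    dgamma(p$tau[tr$root], 5, 100, log = TRUE) - log(p$tau[tr$root]) +
    sum(dgamma(p$M, 2, 10, log = TRUE))
  expect_equal(log_prior(p, pr, tr, mig), manual, tolerance = 1e-12)
  # a single exponential theta: log(100) - 1 at theta = 0.01
  tr1 <- species_tree("(A, B)R;")
  m0 <- migration_spec(tr1)
  pr1 <- prior_spec(1, 100, 1, 100, 2, 10)
  p1 <- param_set(tr1, m0, tau = c(R = 0.01),
                  theta = c(A = 0.01, B = 0.01, R = 0.01))
  expect_equal(log_prior(p1, pr1, tr1, m0),
               3 * (log(100) - 1) + dgamma(0.01, 1, 100, log = TRUE),
               tolerance = 1e-12)
})

test_that("simulated gene trees satisfy every structural invariant", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  set.seed(11)
  for (i in 1:400) {
    gt <- sim_gene_tree(tr, mig, pp, seqs = sample(1:3, 1))
    expect_identical(check_gene_tree(gt, tr, mig, pp), character(0))
  }
})
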