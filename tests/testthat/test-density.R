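test_that("single-pair coalescent density matches the closed form", {
  # one population, two sequences coalescing at t: log(2/theta) - 2t/theta
  tr <- species_tree("(A, B)R;")
  m0 <- migration_spec(tr)
  pp <- param_set(tr, m0, tau = c(R = 1),
                  theta = c(A = 0.01, B = 0.01, R = 0.01))
  # collapse to a single population by making the divergence immediate
  pp2 <- param_set(tr, m0, tau = c(R = 1e-12),
                   theta = c(A = 0.01, B = 0.01, R = 0.01))
  gt <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                  time = c(0, 0, 0.005), pop = c(1L, 2L, 3L))
  expect_equal(log_density_mscm(gt, tr, m0, pp2),
               log(200) - 1, tolerance = 1e-8)
})

test_that("general density equals the hand-coded worked-example density", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  set.seed(101)
  for (i in 1:100) {
    pp <- param_set(tr, mig, tau = c(R = 0.02, S = 0.01),
                    theta = stats::setNames(runif(5, 0.005, 0.05), tr$labels),
                    M = stats::setNames(runif(2, 0.01, 2), c("B->C", "C->B")))
    tm <- worked_example_times()
    gt <- gene_tree_worked_example(tr, pp, tm$t, tm$s)
    expect_identical(check_gene_tree(gt, tr, mig, pp), character(0))
    expect_equal(log_density_mscm(gt, tr, mig, pp),
                 log_density_worked_example(tr, pp, tm$t, tm$s),
                 tolerance = 1e-10)
  }
})

test_that("worked-example decomposition has the expected segment structure", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  s <- c(0.006, 0.008)
  gt <- gene_tree_worked_example(tr, pp, c(0.002, 0.004, 0.013, 0.025, 0.04), s)
  d <- decompose(gt, tr, mig, pp)
  B <- pop_index(tr, "B")
  segB <- d$segments[d$segments$pop == B, ]
  expect_equal(segB$t0, c(0, s[1], s[2]))
  expect_equal(segB$t1, c(s[1], s[2], 0.01))
  expect_equal(segB$n, c(2L, 1L, 2L))
  # one inbound C->B migration event counted in B
  eCB <- which(mig$from == "C" & mig$to == "B")
  expect_equal(d$mig_counts[eCB], 1L)
  # counts add up: coalescences = n_seq - 1, events = rows of the history
  expect_equal(sum(d$coal_counts), gt$ntip - 1L)
  expect_equal(sum(d$mig_counts), nrow(gt$events))
})

test_that("decomposition invariants hold on simulated genealogies", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  set.seed(5)
  for (i in 1:200) {
    gt <- sim_gene_tree(tr, mig, pp, seqs = 2)
    d <- decompose(gt, tr, mig, pp)
    expect_equal(sum(d$coal_counts), gt$ntip - 1L)
    expect_equal(sum(d$mig_counts), nrow(gt$events))
    expect_true(all(d$segments$duration >= 0))
    # per-population lineage-time equals the sum over lineage paths
    seg <- d$segments
    for (j in seq_len(tr$npop)) {
      tot <- sum(seg$n[seg$pop == j] * seg$duration[seg$pop == j])
      expect_gte(tot, 0)
    }
  }
})

test_that("with no migration the density reduces to the plain MSC density", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig, MBC = 0, MCB = 0)
  m0 <- migration_spec(tr)
  pp0 <- param_set(tr, m0, tau = c(R = 0.02, S = 0.01),
                   theta = stats::setNames(pp$theta, tr$labels))
  set.seed(8)
  for (i in 1:100) {
    gt <- sim_gene_tree(tr, m0, pp0, seqs = 2)
    expect_equal(log_density_mscm(gt, tr, mig, pp),
                 msc_only_logdens(gt, tr, pp0), tolerance = 1e-9)
  }
})

test_that("the engine's internal density agrees with the R implementation", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  set.seed(21)
  for (i in 1:50) {
    gt <- sim_gene_tree(tr, mig, pp, seqs = 2)
    st <- mscmig:::cpp_density_stats(
      mscmig:::engine_model(tr, mig, pp, pr),
      mscmig:::engine_locus(gt, NULL))
    expect_equal(st$logG, log_density_mscm(gt, tr, mig, pp),
                 tolerance = 1e-9)
  }
})

test_that("heredity scalars rescale population sizes exactly", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  set.seed(31)
  gt <- sim_gene_tree(tr, mig, pp, seqs = 2, h = 0.75)
  scaled <- pp
  scaled$theta <- pp$theta * 0.75
  # note: heredity scales migration rates like coalescence by default, and
  # M enters as 4M/(theta h), so theta -> theta*h with h -> 1 preserves it
  expect_equal(log_density_mscm(gt, tr, mig, pp, h = 0.75),
               log_density_mscm(gt, tr, mig, scaled, h = 1),
               tolerance = 1e-10)
})

test_that("rescaling all times and sizes shifts the density analytically", {
  # under t -> ct, theta -> c*theta, tau -> c*tau the density picks up a
  # factor c^-(n_coal + n_mig events) (each event rate scales as 1/c while
  # exposures are invariant)
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  set.seed(41)
  gt <- sim_gene_tree(tr, mig, pp, seqs = 2)
  cfac <- 2.5
  gt2 <- gt
  gt2$time <- gt$time * cfac
  gt2$events$time <- gt$events$time * cfac
  pp2 <- pp
  pp2$tau <- pp$tau * cfac
  pp2$theta <- pp$theta * cfac
  nev <- (gt$ntip - 1L) + nrow(gt$events)
  expect_equal(log_density_mscm(gt2, tr, mig, pp2),
               log_density_mscm(gt, tr, mig, pp) - nev * log(cfac),
               tolerance = 1e-9)
})

test_that("events on a zero-rate entry give density zero", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig, MBC = 0.2, MCB = 0.1)
  tm <- list(t = c(0.002, 0.004, 0.013, 0.025, 0.04), s = c(0.006, 0.008))
  gt <- gene_tree_worked_example(tr, pp, tm$t, tm$s)
  pp0 <- bc_params(tr, mig, MBC = 0, MCB = 0)
  expect_identical(log_density_mscm(gt, tr, mig, pp0), -Inf)
})

test_that("phi0 conversion behaves as the closed form", {
  expect_equal(phi0(0, 0.01, 0.01), 0)
  expect_equal(phi0(0.1, 0.01, 0.01), 1 - exp(-0.4), tolerance = 1e-12)
  expect_error(phi0(0.1, 0.01, 0), "theta")
  Ms <- seq(0, 5, by = 0.25)
  v <- phi0(Ms, 0.01, 0.01)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 1))
  expect_gt(phi0(100, 0.01, 0.01), 0.999)
})

test_that("the density integrates to one over genealogies", {
  # importance check: trees simulated under proposal parameters, weighted by
  # density(target)/density(proposal), must average to 1
  tr <- species_tree("(B, C)R;")
  mig <- migration_spec(tr, "B", "C")
  target <- param_set(tr, mig, tau = c(R = 0.05),
                      theta = c(B = 0.01, C = 0.012, R = 0.01), M = 0.3)
  proposal <- param_set(tr, mig, tau = c(R = 0.05),
                        theta = c(B = 0.012, C = 0.01, R = 0.011), M = 0.22)
  set.seed(71)
  w <- replicate(4000, {
    gt <- sim_gene_tree(tr, mig, proposal, seqs = 1)
    exp(log_density_mscm(gt, tr, mig, target) -
        log_density_mscm(gt, tr, mig, proposal))
  })
  se <- sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 1), 3 * se)
})
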