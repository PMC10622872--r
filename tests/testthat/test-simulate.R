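test_that("pair coalescent time has mean theta/2", {
  tr <- species_tree("(A, B)R;")
  m0 <- migration_spec(tr)
  pp <- param_set(tr, m0, tau = c(R = 1e-12),
                  theta = c(A = 0.01, B = 0.01, R = 0.01))
  set.seed(3)
  n <- 2e4
  tt <- replicate(n, max(sim_gene_tree(tr, m0, pp, seqs = 1)$time))
  # exponential(2/theta): mean 0.005, sd 0.005
  expect_lt(abs(mean(tt) - 0.005), 3 * 0.005 / sqrt(n))
})

test_that("an inactive migration entry generates no events", {
  tr4 <- species_tree("((A, B)S, (C, D)T)R;")
  mig4 <- migration_spec(tr4, "S", "C")
  pp <- param_set(tr4, mig4, tau = c(R = 0.03, S = 0.021, T = 0.02),
                  theta = stats::setNames(rep(0.01, 7), tr4$labels), M = 1)
  set.seed(4)
  for (i in 1:200) {
    gt <- sim_gene_tree(tr4, mig4, pp, seqs = 1)
    expect_equal(nrow(gt$events), 0L)
  }
  # and the active configuration does generate them
  pp2 <- param_set(tr4, mig4, tau = c(R = 0.03, S = 0.005, T = 0.02),
                   theta = stats::setNames(rep(0.01, 7), tr4$labels), M = 1)
  set.seed(5)
  tot <- sum(replicate(200, nrow(sim_gene_tree(tr4, mig4, pp2, seqs = 1)$events)))
  expect_gt(tot, 0)
})

test_that("lineage migration frequency matches the phi0 closed form", {
  # one sequence from Q, entry R -> Q: the Q lineage leaves Q before tau_d
  # with probability phi0 = 1 - exp(-4 M tau_d / theta)
  tr <- species_tree("(Q, R)D;")
  mig <- migration_spec(tr, "R", "Q")
  M <- 0.1; tau_d <- 0.01; thQ <- 0.01
  pp <- param_set(tr, mig, tau = c(D = tau_d),
                  theta = c(Q = thQ, R = 0.01, D = 0.01), M = M)
  set.seed(6)
  n <- 2e4
  hits <- replicate(n, {
    gt <- sim_gene_tree(tr, mig, pp, seqs = c(Q = 1, R = 1))
    any(gt$events$time < tau_d & gt$events$node == 1L)
  })
  p0 <- phi0(M, tau_d, thQ)
  expect_lt(abs(mean(hits) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("JC69 sequence simulation reproduces the divergence curve", {
  tr <- species_tree("(A, B)R;")
  m0 <- migration_spec(tr)
  pp <- param_set(tr, m0, tau = c(R = 1e-12),
                  theta = c(A = 0.01, B = 0.01, R = 0.01))
  gt <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                  time = c(0, 0, 0.05), pop = c(1L, 2L, 3L),
                  labels = c("A^1", "B^1"))
  set.seed(7)
  loc <- sim_alignment(gt, sites = 5e4)
  d <- 0.1  # total path length between the two tips
  expected <- 0.75 * (1 - exp(-4 * d / 3))
  obs <- mean(loc$seqs[1, ] != loc$seqs[2, ])
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 5e4))
  # zero branch lengths: identical sequences
  gt0 <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                   time = c(0, 0, 0), pop = c(1L, 2L, 3L))
  loc0 <- sim_alignment(gt0, sites = 100)
  expect_identical(loc0$seqs[1, ], loc0$seqs[2, ])
})

test_that("datasets are reproducible and loci use independent streams", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  cfg <- sample_config(loci = 4, seqs = 2, sites = 30)
  d1 <- sim_dataset(tr, mig, pp, cfg, seed = 99)
  d2 <- sim_dataset(tr, mig, pp, cfg, seed = 99)
  expect_identical(d1, d2)
  # locus 3 alone equals locus 3 of the batch
  set.seed(locus_seed(99, 3))
  gt <- sim_gene_tree(tr, mig, pp, cfg$seqs, h = 1)
  expect_identical(gt, d1[[3]]$gene_tree)
  # empty dataset
  expect_length(sim_dataset(tr, mig, pp, sample_config(0, 2, 10), seed = 1), 0L)
})

test_that("topology frequencies match the MSC closed form when M = 0", {
  tr <- three_species_tree()
  m0 <- migration_spec(tr)
  thS <- 0.01; tauR <- 0.02; tauS <- 0.012
  pp <- param_set(tr, m0, tau = c(R = tauR, S = tauS),
                  theta = stats::setNames(c(0.01, 0.01, 0.01, 0.01, thS),
                                          c("A", "B", "C", "R", "S")))
  set.seed(8)
  n <- 1e4
  conc <- replicate(n, {
    gt <- sim_gene_tree(tr, m0, pp, seqs = 1)
    # concordant: a and b coalesce first
    first <- which.min(gt$time[(gt$ntip + 1L):gt$nnode]) + gt$ntip
    ch <- which(gt$parent == first)
    setequal(ch[ch <= 3], c(1L, 2L))
  })
  p <- 1 - (2 / 3) * exp(-2 * (tauR - tauS) / thS)
  expect_lt(abs(mean(conc) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the bayesian replicate couples parameters and data", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pr <- prior_spec(4, 200, 4, 200, 2, 10)
  cfg <- sample_config(loci = 3, seqs = 2, sites = 20)
  rep1 <- sim_bayesian_replicate(pr, tr, mig, cfg, seed = 7)
  rep2 <- sim_bayesian_replicate(pr, tr, mig, cfg, seed = 7)
  expect_identical(rep1, rep2)
  expect_length(rep1$dataset, 3L)
  expect_true(all(rep1$params$theta > 0))
  for (d in rep1$dataset)
    expect_identical(check_gene_tree(d$gene_tree, tr, mig, rep1$params),
                     character(0))
})

test_that("migration events accrue at rate 4M/theta per lineage-time", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig, MBC = 0.4, MCB = 0.15)
  set.seed(81)
  w <- c(0, 0); b <- c(0, 0)
  for (i in 1:1500) {
    d <- decompose(sim_gene_tree(tr, mig, pp, seqs = 2), tr, mig, pp)
    w <- w + d$mig_counts
    b <- b + d$mig_exposure
  }
  # entry e: E[events] = (4 M_e / theta_dst) * E[active lineage-time exposure]
  for (e in 1:2) {
    rate <- 4 * pp$M[e] / pp$theta[mig$dst[e]]
    expect_lt(abs(w[e] / b[e] - rate) / rate, 3 / sqrt(w[e]))
  }
})
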