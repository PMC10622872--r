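test_that("jc69 transition matrix has the closed form and limits", {
  expect_equal(jc69_transition(0), diag(4), ignore_attr = TRUE)
  expect_equal(unname(jc69_transition(1e6)), matrix(0.25, 4, 4),
               tolerance = 1e-12)
  P <- jc69_transition(0.1)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-0.4 / 3), tolerance = 1e-12)
  expect_equal(P[1, 1], 0.90638, tolerance = 1e-5)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_error(jc69_transition(-0.1), ">= 0")
})

test_that("site-pattern compression preserves counts and content", {
  seqs <- matrix(c(0L, 1L, 0L, 0L, 1L,
                   0L, 1L, 0L, 0L, 2L,
                   0L, 1L, 0L, 0L, 2L), nrow = 3, byrow = TRUE)
  loc <- structure(list(seqs = seqs, labels = c("A^1", "A^2", "B^1"), h = 1),
                   class = "mscm_locus")
  sp <- site_patterns(loc)
  expect_equal(sum(sp$counts), 5)
  expect_equal(ncol(sp$patterns), 3L)  # (0,0,0) x3, (1,1,1), (1,2,2)
})

test_that("pruning equals the brute-force state sum on 4 taxa", {
  tr <- species_tree("((A, B)S, C)R;")
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  set.seed(12)
  for (i in 1:5) {
    gt <- sim_gene_tree(tr, mig, pp, seqs = c(A = 2, B = 1, C = 1))
    loc <- sim_alignment(gt, sites = 10)
    expect_equal(log_likelihood(loc, gt), brute_force_loglik(loc, gt),
                 tolerance = 1e-10)
  }
})

test_that("two identical sequences give the constant-site closed form", {
  gt <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                  time = c(0, 0, 0.05), pop = c(1L, 2L, 3L),
                  labels = c("A^1", "B^1"))
  loc <- structure(list(seqs = matrix(2L, 2, 7), labels = c("A^1", "B^1"),
                        h = 1), class = "mscm_locus")
  d <- 0.1
  persite <- log(0.25) + log(0.25 + 0.75 * exp(-4 * d / 3))
  expect_equal(log_likelihood(loc, gt), 7 * persite, tolerance = 1e-10)
})

test_that("likelihood ignores migration events at fixed coalescent times", {
  tr <- three_species_tree()
  mig <- bc_migration(tr)
  pp <- bc_params(tr, mig)
  tm <- list(t = c(0.002, 0.004, 0.013, 0.025, 0.04), s = c(0.006, 0.008))
  gt <- gene_tree_worked_example(tr, pp, tm$t, tm$s)
  set.seed(13)
  loc <- sim_alignment(gt, sites = 50)
  base <- log_likelihood(loc, gt)
  gt2 <- gt
  gt2$events <- gt$events[0, ]  # strip the migration history entirely
  gt2$pop[4] <- gt$tip_pop[4]
  expect_equal(log_likelihood(loc, gt2), base, tolerance = 1e-12)
})

test_that("re-rooting along the root edge leaves the likelihood unchanged", {
  # JC69 is reversible: sliding the root along its edge (pulley principle)
  # must not change the likelihood
  # on a 2-taxon tree only the SUM of the two root branches can matter
  gt2t <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                    time = c(0, 0, 0.05), pop = c(1L, 2L, 3L),
                    labels = c("A^1", "B^1"))
  set.seed(15)
  loc2 <- sim_alignment(gt2t, sites = 60)
  # shifting one tip up and the root down, keeping the total path 0.1:
  gt2b <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                    time = c(0, 0.04, 0.07), pop = c(1L, 2L, 3L),
                    labels = c("A^1", "B^1"))
  # path lengths: 0.05+0.05 vs 0.07+0.03 -- both total 0.1
  expect_equal(log_likelihood(loc2, gt2t), log_likelihood(loc2, gt2b),
               tolerance = 1e-10)
})

test_that("label mismatches are rejected", {
  gt <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                  time = c(0, 0, 0.05), pop = c(1L, 2L, 3L),
                  labels = c("A^1", "B^1"))
  loc <- structure(list(seqs = matrix(0L, 2, 5), labels = c("A^1", "B^2"),
                        h = 1), class = "mscm_locus")
  expect_error(log_likelihood(loc, gt), "labels")
})

test_that("missing data contribute flat partial likelihoods", {
  gt <- gene_tree(tip_pop = c(1L, 2L), parent = c(3L, 3L, NA),
                  time = c(0, 0, 0.05), pop = c(1L, 2L, 3L),
                  labels = c("A^1", "B^1"))
  loc <- structure(list(seqs = matrix(c(2L, -1L), 2, 4), labels = c("A^1", "B^1"),
                        h = 1), class = "mscm_locus")
  # sites with one missing base: likelihood is just the root frequency 1/4
  expect_equal(log_likelihood(loc, gt), 4 * log(0.25), tolerance = 1e-12)
})
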