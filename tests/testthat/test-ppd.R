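# Posterior probabilities of disease and their exact population
# distributions, checked against direct Bayes-rule arithmetic and
# exhaustive enumeration.

test_that("single-locus posteriors match direct Bayes-rule computation", {
  m <- exchangeable_model(1, g0 = 0.05, rr = 2, prior = 0.2)
  expect_equal(ppd(m, 1), 0.02 / 0.06)    # carrier: 1/3
  expect_equal(ppd(m, 0), 0.18 / 0.94)    # non-carrier
})

test_that("non-informative loci leave the posterior at the prior", {
  m <- exchangeable_model(50, g0 = 0.1, rr = 1, prior = 0.37)
  set.seed(1)
  g <- matrix(rbinom(500, 1, 0.5), nrow = 10)
  expect_equal(unname(ppd(m, g)), rep(0.37, 10))
})

test_that("degenerate priors are returned exactly", {
  expect_equal(ppd(exchangeable_model(3, 0.1, 2, 0), c(1, 1, 1)), 0)
  expect_equal(ppd(exchangeable_model(3, 0.1, 2, 1), c(0, 0, 0)), 1)
})

test_that("genotype validation catches mismatches", {
  m <- exchangeable_model(3, 0.1, 2, 0.2)
  expect_error(ppd(m, c(1, 0)), "does not match")
  expect_error(ppd(m, c(1, 0, 2)), "0 or 1")
})

test_that("ppd matches the oracle on random heterogeneous profiles", {
  for (seed in 1:5) {
    m <- random_model(8, seed)
    set.seed(seed + 100)
    g <- rbinom(8, 1, 0.5)
    expect_equal(ppd(m, g), oracle_ppd(m$prior, m$loci$g0, m$loci$g1, g),
                 tolerance = 1e-12)
  }
})

test_that("distribution equals exhaustive enumeration in every mode", {
  for (seed in 1:4) {
    m <- random_model(10, seed)
    for (mode in c("marginal_independent", "mixture", "control")) {
      d <- ppd_distribution(m, population_mode = mode)
      o <- oracle_ppd_distribution(m, mode)
      expect_lt(tv_distance(d, o), 1e-6)
    }
  }
})

test_that("exchangeable engine agrees with enumeration at small n", {
  m <- exchangeable_model(8, 0.15, 1.8, 0.25)
  for (mode in c("marginal_independent", "mixture", "control")) {
    d <- ppd_distribution(m, population_mode = mode)
    o <- oracle_ppd_distribution(m, mode)
    expect_lt(tv_distance(d, o), 1e-6)
    expect_equal(d$combinations, o$count, tolerance = 1e-9)
  }
})

test_that("grid-binned large models agree with the exchangeable route", {
  # force the heterogeneous grid path on an exchangeable architecture by
  # perturbing one locus infinitesimally, then compare C1/C2 fractions
  n <- 30
  loci <- lapply(seq_len(n), function(i) {
    locus_effect(0.1 + (i == 1) * 1e-9, 1.6, paste0("L", i))
  })
  het <- disease_model(loci, 0.2)
  expect_false(het$exchangeable)
  exch <- exchangeable_model(n, 0.1, 1.6, 0.2)
  dh <- ppd_distribution(het, resolution = 8192)
  de <- ppd_distribution(exch)
  for (tau in c(0.1, 0.3, 0.6)) {
    th <- threshold_fractions(dh, tau_pos = 0.95, tau_neg = tau)
    te <- threshold_fractions(de, tau_pos = 0.95, tau_neg = tau)
    expect_equal(th$c2_fraction, te$c2_fraction, tolerance = 1e-3)
  }
})

test_that("distribution mass conserves and support is valid", {
  for (seed in 1:3) {
    m <- random_model(6, seed, mode = "mixture")
    d <- ppd_distribution(m)
    expect_lt(abs(sum(d$mass) - 1), 1e-9)
    expect_true(all(d$mass >= 0))
    expect_true(all(diff(d$support) > 0))
    expect_true(all(d$support >= 0 & d$support <= 1))
  }
})

test_that("mixture-mode mean posterior equals the prior", {
  # law of total expectation holds for the generative population only
  m <- exchangeable_model(200, 0.07, 1.9, 0.23, population_mode = "mixture")
  expect_equal(ppd_mean(ppd_distribution(m)), 0.23, tolerance = 1e-9)
  het <- random_model(9, 3, prior = 0.31, mode = "mixture")
  expect_equal(ppd_mean(ppd_distribution(het)), 0.31, tolerance = 1e-9)
})

test_that("posterior is strictly increasing in carrier count when rr > 1", {
  m <- exchangeable_model(100, 0.1, 1.3, 0.2)
  d <- ppd_distribution(m)
  expect_length(d$support, 101)
  expect_true(all(diff(d$support) > 0))
})

test_that("marginal_independent and mixture modes coincide at one locus", {
  m <- exchangeable_model(1, 0.05, 2, 0.2)
  a <- ppd_distribution(m, population_mode = "marginal_independent")
  b <- ppd_distribution(m, population_mode = "mixture")
  expect_equal(a$support, b$support)
  expect_equal(a$mass, b$mass, tolerance = 1e-12)
})

test_that("threshold fractions are strict, consistent, and sum to one", {
  # degenerate distribution at the prior: thresholds never strictly crossed
  m0 <- exchangeable_model(10, 0.1, 1, 0.2)
  tf <- threshold_fractions(ppd_distribution(m0), 0.95, 0.05)
  expect_equal(tf$c1_fraction, 0)
  expect_equal(tf$c2_fraction, 0)
  expect_equal(tf$neither_fraction, 1)

  # mass exactly at a threshold belongs to neither condition
  m1 <- exchangeable_model(10, 0.1, 1, 0.2)
  tf2 <- threshold_fractions(ppd_distribution(m1), tau_pos = 0.5,
                             tau_neg = 0.2)
  expect_equal(tf2$c2_fraction, 0)

  expect_error(threshold_fractions(ppd_distribution(m0), 0.05, 0.95),
               "tau")

  # against enumeration on a 3-locus model
  m3 <- random_model(3, 11)
  d3 <- ppd_distribution(m3)
  o3 <- oracle_ppd_distribution(m3)
  tf3 <- threshold_fractions(d3, 0.4, 0.2)
  expect_equal(tf3$c1_fraction, sum(o3$mass[o3$support > 0.4]),
               tolerance = 1e-12)
  expect_equal(tf3$c2_fraction, sum(o3$mass[o3$support < 0.2]),
               tolerance = 1e-12)
  expect_equal(tf3$c1_fraction + tf3$c2_fraction + tf3$neither_fraction, 1,
               tolerance = 1e-9)
})

test_that("relative-risk sweep reproduces limiting cases", {
  sw <- sweep_relative_risk(100, 0.05, 0.2, rr_grid = 1)
  expect_equal(sw$c1, 0)
  expect_equal(sw$c2, 0)
})

test_that("prior sweep handles degenerate priors via stated limits", {
  sw <- sweep_prior(100, 0.05, 2.0, c(0, 0.001, 0.5, 1))
  expect_gt(sw$c2[sw$prior == 0], 0.99)
  expect_gt(sw$c2[sw$prior == 0.001], 0.9)
  expect_gt(sw$c1[sw$prior == 1], 0.99)
  # around an even prior most subjects satisfy neither condition
  expect_gt(sw$neither[sw$prior == 0.5], 0.5)
})

test_that("locus-count sweep reports two-point variance correctly at n=1", {
  sw <- sweep_locus_count(0.05, 2.0, 0.2, 1)
  g_pop <- 0.2 * 0.1 + 0.8 * 0.05
  p1 <- 0.02 / 0.06; p0 <- 0.18 / 0.94
  mu <- g_pop * p1 + (1 - g_pop) * p0
  expect_equal(sw$ppd_variance,
               g_pop * (p1 - mu)^2 + (1 - g_pop) * (p0 - mu)^2,
               tolerance = 1e-12)
  # and rr = 1 collapses the variance for any n
  sw0 <- sweep_locus_count(0.05, 1, 0.2, c(5, 50))
  expect_equal(sw0$ppd_variance, c(0, 0))
})

test_that("scaled posterior ratios are anchored at one", {
  m <- random_model(3, 21)
  combos <- as.matrix(expand.grid(rep(list(0:1), 3)))
  srr <- scaled_posterior_ratios(m, combos)
  expect_equal(min(srr), 1)
  pv <- apply(combos, 1, function(g)
    oracle_ppd(m$prior, m$loci$g0, m$loci$g1, g))
  expect_equal(srr, pv / min(pv), tolerance = 1e-12)

  # identical profiles give all-ones
  same <- matrix(rep(c(1, 0, 1), 4), nrow = 4, byrow = TRUE)
  expect_equal(scaled_posterior_ratios(m, same), rep(1, 4))
  expect_error(scaled_posterior_ratios(m, matrix(numeric(0), 0, 3)),
               "non-empty")
})
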