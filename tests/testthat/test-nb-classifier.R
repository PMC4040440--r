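# Naive Bayes genotype classifier: estimation, prediction, cross-validation.

# small deterministic two-class cohort: 8/10 vs 2/10 carriers at one locus
two_class_cohort <- function() {
  g <- matrix(c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8)), ncol = 1,
              dimnames = list(NULL, "L1"))
  cohort(g, rep(c("case", "control"), each = 10))
}

test_that("fitting without smoothing recovers raw frequencies", {
  fit <- nb_fit(two_class_cohort(), pseudocount = 0)
  expect_equal(fit$freq$L1["1", "case"], 0.8)
  expect_equal(fit$freq$L1["1", "control"], 0.2)
  expect_equal(fit$priors, c(0.5, 0.5))
})

test_that("additive smoothing follows the stated rule", {
  g <- matrix(rep(0L, 20), ncol = 1, dimnames = list(NULL, "L1"))
  g[11:20, 1] <- rep(c(0L, 1L), 5)
  x <- cohort(g, rep(c("a", "b"), each = 10))
  fit <- nb_fit(x, pseudocount = 1)
  # class a: 0 carriers of 10, binary states -> (0+1)/(10+2)
  expect_equal(fit$freq$L1["1", "a"], 1 / 12)
  expect_equal(sum(fit$freq$L1[, "a"]), 1)
})

test_that("fit recovers generating frequencies at large n", {
  freq <- list(
    L1 = matrix(c(0.7, 0.2, 0.1, 0.2, 0.5, 0.3, 0.1, 0.2, 0.7), 3,
                dimnames = list(0:2, c("A", "B", "C"))),
    L2 = matrix(c(0.5, 0.5, 0.9, 0.1, 0.3, 0.7), 2,
                dimnames = list(0:1, c("A", "B", "C")))
  )
  tab <- class_table(freq, c(A = 0.3, B = 0.3, C = 0.4))
  co <- simulate_multiclass(tab, c(A = 16000, B = 16000, C = 18000),
                            seed = 77)
  fit <- nb_fit(co, pseudocount = 0)
  for (loc in names(freq)) {
    for (cl in c("A", "B", "C")) {
      n_cl <- sum(co$labels == cl)
      for (s in rownames(freq[[loc]])) {
        p <- freq[[loc]][s, cl]
        se <- sqrt(p * (1 - p) / n_cl)
        expect_lt(abs(fit$freq[[loc]][s, cl] - p), 3 * se + 1e-12)
      }
    }
  }
})

test_that("posteriors are normalised and respond to evidence", {
  fit <- nb_fit(two_class_cohort(), pseudocount = 0.5)
  post <- nb_predict(fit, matrix(c(1L, 0L), 2, 1,
                                 dimnames = list(NULL, "L1")))
  expect_equal(unname(rowSums(post)), c(1, 1), tolerance = 1e-9)
  expect_gt(post[1, "case"], post[2, "case"])

  # loci with identical state frequencies in both classes: posteriors
  # stay at the priors
  g <- matrix(rep(c(0L, 1L), each = 10), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  x <- cohort(g, rep(c("u", "v"), 5))
  p0 <- nb_predict(nb_fit(x, pseudocount = 0), rbind(c(a = 0L, b = 1L)))
  expect_equal(unname(p0[1, ]), c(0.5, 0.5))
})

test_that("binary classifier equals the PPD engine on matched parameters", {
  m <- random_model(6, 13, prior = 0.2)
  freq <- lapply(seq_len(6), function(j) {
    matrix(c(1 - m$loci$g0[j], m$loci$g0[j],
             1 - m$loci$g1[j], m$loci$g1[j]), 2,
           dimnames = list(0:1, c("control", "case")))
  })
  names(freq) <- m$loci$locus_id
  tab <- class_table(freq, c(control = 0.8, case = 0.2))
  set.seed(99)
  for (i in 1:20) {
    g <- rbinom(6, 1, 0.5)
    gm <- matrix(g, 1, dimnames = list(NULL, m$loci$locus_id))
    expect_equal(unname(nb_predict(tab, gm)[1, "case"]), ppd(m, g),
                 tolerance = 1e-12)
  }
})

test_that("a perfectly class-specific state forces a certain call", {
  freq <- list(L1 = matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3,
                           dimnames = list(0:2, c("A", "B", "C"))))
  tab <- class_table(freq, c(A = 1 / 3, B = 1 / 3, C = 1 / 3))
  post <- nb_predict(tab, matrix(1L, 1, 1, dimnames = list(NULL, "L1")))
  expect_equal(unname(post[1, ]), c(0, 1, 0))
})

test_that("infinite smoothing collapses posteriors to the class priors", {
  x <- two_class_cohort()
  fit <- nb_fit(x, pseudocount = 1e9, priors = c(case = 0.3, control = 0.7))
  post <- nb_predict(fit, matrix(1L, 1, 1, dimnames = list(NULL, "L1")))
  expect_equal(unname(post[1, "case"]), 0.3, tolerance = 1e-6)
})

test_that("missing genotypes skip their locus; unseen states are reported", {
  x <- two_class_cohort()
  fit <- nb_fit(x, pseudocount = 0)
  post_na <- nb_predict(fit, matrix(NA_integer_, 1, 1,
                                    dimnames = list(NULL, "L1")))
  expect_equal(unname(post_na[1, ]), c(0.5, 0.5))  # only the prior remains
  expect_error(nb_predict(fit, matrix(2L, 1, 1,
                                      dimnames = list(NULL, "L1"))),
               "not present")
})

test_that("all-missing loci in a class are dropped with a warning", {
  g <- cbind(L1 = c(0L, 1L, 0L, 1L), L2 = c(NA, NA, 0L, 1L))
  x <- cohort(g, c("a", "a", "b", "b"))
  expect_warning(fit <- nb_fit(x), "L2")
  expect_equal(fit$loci, "L1")
})

test_that("cross-validation folds partition the cohort, stratified", {
  freq <- list(L1 = matrix(c(0.8, 0.2, 0.3, 0.7), 2,
                           dimnames = list(0:1, c("a", "b"))))
  tab <- class_table(freq, c(a = 0.5, b = 0.5))
  co <- simulate_multiclass(tab, c(a = 50, b = 30), seed = 3)
  cv <- nb_cross_validate(co, k = 5, seed = 42)
  expect_equal(length(cv$folds), 80)
  expect_true(all(tabulate(cv$folds, 5) == 16))       # partition
  for (f in 1:5) {  # stratification: 10 of a, 6 of b per fold
    expect_equal(sum(co$labels[cv$folds == f] == "a"), 10)
  }
  # deterministic under the seed
  cv2 <- nb_cross_validate(co, k = 5, seed = 42)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$accuracy, cv2$accuracy)
  expect_error(nb_cross_validate(co, k = 40), "at least k")
})

test_that("a separable cohort cross-validates perfectly", {
  freq <- list(L1 = matrix(c(1, 0, 0, 1), 2,
                           dimnames = list(0:1, c("a", "b"))))
  tab <- class_table(freq, c(a = 0.5, b = 0.5))
  co <- simulate_multiclass(tab, c(a = 40, b = 40), seed = 1)
  cv <- nb_cross_validate(co, k = 4, seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auc, 1)
})

test_that("label permutation yields null performance", {
  m <- exchangeable_model(10, 0.2, 1.6, 0.5)
  co <- simulate_case_control(m, 2500, 2500, seed = 12)
  set.seed(13)
  co_null <- cohort(co$genotypes, sample(co$labels))
  cv <- nb_cross_validate(co_null, k = 5, seed = 14)
  expect_lt(abs(cv$auc - 0.5), 0.03)
})

test_that("3-class CV accuracy approaches the enumerated Bayes accuracy", {
  freq <- list(
    L1 = matrix(c(0.8, 0.2, 0.4, 0.6, 0.15, 0.85), 2,
                dimnames = list(0:1, c("A", "B", "C"))),
    L2 = matrix(c(0.7, 0.3, 0.2, 0.8, 0.5, 0.5), 2,
                dimnames = list(0:1, c("A", "B", "C"))),
    L3 = matrix(c(0.6, 0.4, 0.3, 0.7, 0.8, 0.2), 2,
                dimnames = list(0:1, c("A", "B", "C")))
  )
  priors <- c(A = 1 / 3, B = 1 / 3, C = 1 / 3)
  tab <- class_table(freq, priors)
  # Bayes accuracy by brute-force enumeration over all 2^3 profiles
  combos <- as.matrix(expand.grid(rep(list(0:1), 3)))
  bayes_acc <- 0
  for (i in seq_len(nrow(combos))) {
    like <- vapply(c("A", "B", "C"), function(cl) {
      prod(vapply(1:3, function(j) {
        freq[[j]][as.character(combos[i, j]), cl]
      }, numeric(1)))
    }, numeric(1))
    joint <- priors * like
    bayes_acc <- bayes_acc + max(joint)  # P(profile, best class correct)
  }
  co <- simulate_multiclass(tab, c(A = 2000, B = 2000, C = 2000), seed = 55)
  cv <- nb_cross_validate(co, k = 5, seed = 56)
  se <- sqrt(bayes_acc * (1 - bayes_acc) / 6000)
  expect_lt(abs(cv$accuracy - bayes_acc), 3 * se + 0.01)
})
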