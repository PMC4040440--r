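# Posterior probability of disease (PPD) under the Naive Bayes factorisation,
# and its exact distribution over a stated population.
#
# For a genotype profile G1..Gn with conditionally independent loci,
#   logit P(D=1 | G) = logit(K) + sum_i [ Gi * ln(lr_pos_i)
#                                         + (1 - Gi) * ln(lr_neg_i) ]
# with K the disease prior. All accumulation is in log space, so models with
# up to 1e5 loci neither under- nor overflow.

#' Posterior probability of disease for genotype profiles
#'
#' Computes `P(D = 1 | G1..Gn)` under the Naive Bayes model: the prior odds
#' are multiplied by the carrier likelihood ratio `g1/g0` at each carried
#' locus and by the non-carrier ratio `(1-g1)/(1-g0)` elsewhere.
#' Computation is in log space.
#'
#' @param model A [disease_model()].
#' @param genotype A binary vector of length `n_loci` (1 = carries the
#'   predisposing genotype), or a matrix with one such row per subject.
#' @return A probability per profile, in \[0, 1\]. A prior of exactly 0 or 1
#'   is returned unchanged regardless of genotype.
#' @examples
#' m <- exchangeable_model(1, g0 = 0.05, rr = 2, prior = 0.2)
#' ppd(m, 1)  # 1/3: carrier at a doubling locus
#' ppd(m, 0)  # 0.1914894
#' @export
ppd <- function(model, genotype) {
  stopifnot(inherits(model, "disease_model"))
  n <- nrow(model$loci)
  if (is.matrix(genotype)) {
    if (ncol(genotype) != n) {
      stop("genotype matrix has ", ncol(genotype), " columns; model has ",
           n, " loci")
    }
    return(apply(genotype, 1L, function(g) ppd(model, g)))
  }
  if (length(genotype) != n) {
    stop("genotype length ", length(genotype), " does not match ", n, " loci")
  }
  if (!all(genotype %in% c(0, 1))) stop("genotype entries must be 0 or 1")
  if (model$prior == 0 || model$prior == 1) return(model$prior)
  llr <- sum(ifelse(genotype == 1,
                    log(model$loci$lr_pos), log(model$loci$lr_neg)))
  stats::plogis(stats::qlogis(model$prior) + llr)
}

.ppd_from_llr <- function(prior, llr) {
  stats::plogis(stats::qlogis(prior) + llr)
}

#' Exact population distribution of the posterior probability of disease
#'
#' Computes the discrete distribution of PPD values over the population named
#' by the model's `population_mode`. For exchangeable models the PPD depends
#' only on the carrier count `k`, whose population law is binomial
#' (`control`: Binomial(n, g0); `marginal_independent`: Binomial(n, g_pop);
#' `mixture`: the prior-weighted mixture of Binomial(n, g1) and
#' Binomial(n, g0)), so models with thousands of loci are exact. For
#' heterogeneous models with `n <= 20` loci the per-locus log-likelihood-ratio
#' increments are convolved exactly (equal values merged); above 20 loci a
#' fixed-width dynamic-programming grid of `resolution` bins over the
#' log-likelihood-ratio range is used, with the per-bin discretisation step
#' recorded on the result.
#'
#' @param model A [disease_model()].
#' @param resolution Number of log-LR bins for large heterogeneous models
#'   (>= 256; default 4096).
#' @param population_mode Optional override of the model's mode.
#' @return An object of class `ppd_distribution`: list with `support`
#'   (strictly ascending PPD values), `mass` (summing to 1),
#'   `combinations` (number of multilocus genotype combinations mapped to
#'   each support point, `NA` for grid-binned results), `population_mode`,
#'   `prior`, `n_loci`, `model_digest`, and `grid_step` (0 when exact).
#' @export
ppd_distribution <- function(model, resolution = 4096L,
                             population_mode = NULL) {
  stopifnot(inherits(model, "disease_model"))
  mode <- if (is.null(population_mode)) model$population_mode else
    match.arg(population_mode,
              c("marginal_independent", "mixture", "control"))
  n <- nrow(model$loci)
  if (n > 100000L) stop("models above 100,000 loci are not supported")
  resolution <- as.integer(resolution)
  if (resolution < 256L) stop("resolution must be at least 256")

  if (model$exchangeable) {
    out <- .ppd_dist_exchangeable(model, mode)
  } else if (n <= 20L) {
    out <- .ppd_dist_exact(model, mode)
  } else {
    out <- .ppd_dist_grid(model, mode, resolution)
  }
  out$population_mode <- mode
  out$prior <- model$prior
  out$n_loci <- n
  out$model_digest <- .model_digest(model)
  class(out) <- "ppd_distribution"
  out
}

.ppd_dist_exchangeable <- function(model, mode) {
  n <- nrow(model$loci)
  g0 <- model$loci$g0[1]; g1 <- model$loci$g1[1]
  prior <- model$prior
  k <- 0:n
  if (prior == 0 || prior == 1) {
    support <- prior
  } else {
    llr <- k * log(model$loci$lr_pos[1]) + (n - k) * log(model$loci$lr_neg[1])
    support <- .ppd_from_llr(prior, llr)
  }
  mass <- switch(mode,
    control = stats::dbinom(k, n, g0),
    marginal_independent = stats::dbinom(k, n,
                                         prior * g1 + (1 - prior) * g0),
    mixture = prior * stats::dbinom(k, n, g1) +
      (1 - prior) * stats::dbinom(k, n, g0))
  combos <- exp(lchoose(n, k))
  .finish_dist(rep_len(support, n + 1L), mass, combos, grid_step = 0)
}

# Exact convolution of per-locus two-point log-LR increments, merging equal
# sums so exchangeable-like substructure never blows up the support.
.llr_convolve_exact <- function(lp, ln, p_carrier) {
  llr <- 0; pr <- 1; cnt <- 1
  for (i in seq_along(p_carrier)) {
    llr <- c(llr + ln[i], llr + lp[i])
    pr <- c(pr * (1 - p_carrier[i]), pr * p_carrier[i])
    cnt <- c(cnt, cnt)
    key <- factor(signif(llr, 12))
    pr <- rowsum(pr, key, reorder = TRUE)[, 1]
    cnt <- rowsum(cnt, key, reorder = TRUE)[, 1]
    llr <- as.numeric(levels(key))
  }
  o <- order(llr)
  list(llr = llr[o], prob = pr[o], count = cnt[o])
}

.ppd_dist_exact <- function(model, mode) {
  l <- model$loci
  lp <- log(l$lr_pos); ln <- log(l$lr_neg)
  if (mode == "mixture") {
    d1 <- .llr_convolve_exact(lp, ln, l$g1)
    d0 <- .llr_convolve_exact(lp, ln, l$g0)
    llr <- c(d1$llr, d0$llr)
    pr <- c(model$prior * d1$prob, (1 - model$prior) * d0$prob)
    cnt <- c(d1$count, rep(0, length(d0$count)))  # same genotype space
    key <- factor(signif(llr, 12))
    pr <- rowsum(pr, key, reorder = TRUE)[, 1]
    cnt <- rowsum(cnt, key, reorder = TRUE)[, 1]
    llr <- as.numeric(levels(key))
    d <- list(llr = llr, prob = pr, count = pmax(cnt, 1))
  } else {
    p <- .carrier_prob(model, mode)
    d <- .llr_convolve_exact(lp, ln, p)
  }
  support <- if (model$prior %in% c(0, 1)) rep(model$prior, length(d$llr))
             else .ppd_from_llr(model$prior, d$llr)
  .finish_dist(support, d$prob, d$count, grid_step = 0)
}

# Fixed-grid dynamic programming over log-LR sums for large heterogeneous
# models. Each locus contributes a two-point increment; increments are
# snapped to the grid step, giving a worst-case discretisation error of
# n * step / 2 on the log-odds scale (reported via grid_step).
.llr_convolve_grid <- function(lp, ln, p_carrier, resolution) {
  a <- pmin(lp, ln)
  lo <- sum(a); hi <- sum(pmax(lp, ln))
  if (hi - lo < 1e-14) {
    return(list(llr = lo, prob = 1, step = 0))
  }
  step <- (hi - lo) / (resolution - 1L)
  s0 <- as.integer(round((ln - a) / step))
  s1 <- as.integer(round((lp - a) / step))
  width <- resolution + length(p_carrier) + 1L  # rounding slack
  mass <- numeric(width); mass[1L] <- 1
  for (i in seq_along(p_carrier)) {
    m0 <- m1 <- numeric(width)
    if (s0[i] == 0L) m0 <- mass else
      m0[(s0[i] + 1L):width] <- mass[1:(width - s0[i])]
    if (s1[i] == 0L) m1 <- mass else
      m1[(s1[i] + 1L):width] <- mass[1:(width - s1[i])]
    mass <- (1 - p_carrier[i]) * m0 + p_carrier[i] * m1
  }
  keep <- which(mass > 0)
  list(llr = lo + (keep - 1L) * step, prob = mass[keep], step = step)
}

.ppd_dist_grid <- function(model, mode, resolution) {
  l <- model$loci
  lp <- log(l$lr_pos); ln <- log(l$lr_neg)
  if (mode == "mixture") {
    d1 <- .llr_convolve_grid(lp, ln, l$g1, resolution)
    d0 <- .llr_convolve_grid(lp, ln, l$g0, resolution)
    llr <- c(d1$llr, d0$llr)
    pr <- c(model$prior * d1$prob, (1 - model$prior) * d0$prob)
    key <- factor(signif(llr, 12))
    pr <- rowsum(pr, key, reorder = TRUE)[, 1]
    llr <- as.numeric(levels(key))
    d <- list(llr = llr, prob = pr, step = max(d1$step, d0$step))
  } else {
    d <- .llr_convolve_grid(lp, ln, .carrier_prob(model, mode), resolution)
  }
  support <- if (model$prior %in% c(0, 1)) rep(model$prior, length(d$llr))
             else .ppd_from_llr(model$prior, d$llr)
  .finish_dist(support, d$prob, rep(NA_real_, length(support)),
               grid_step = d$step)
}

# Sort ascending, merge duplicate PPD values, renormalise away rounding.
.finish_dist <- function(support, mass, combinations, grid_step) {
  o <- order(support)
  support <- support[o]; mass <- mass[o]; combinations <- combinations[o]
  key <- factor(signif(support, 14), levels = unique(signif(support, 14)))
  mass <- rowsum(mass, key, reorder = FALSE)[, 1]
  combinations <- rowsum(combinations, key, reorder = FALSE)[, 1]
  support <- support[!duplicated(key)]
  total <- sum(mass)
  if (abs(total - 1) > 1e-9) {
    stop("internal error: distribution mass sums to ", total)
  }
  list(support = as.numeric(support), mass = as.numeric(mass / total),
       combinations = as.numeric(combinations), grid_step = grid_step)
}

#' @export
print.ppd_distribution <- function(x, ...) {
  cat(sprintf(
    "<ppd_distribution> %d support points, mode=%s, prior=%g, n_loci=%d\n",
    length(x$support), x$population_mode, x$prior, x$n_loci))
  cat(sprintf("  mean=%g var=%g%s\n", ppd_mean(x), ppd_variance(x),
              if (x$grid_step > 0)
                sprintf(" (grid step %.3g on log-odds)", x$grid_step)
              else ""))
  invisible(x)
}

#' Mean and variance of a PPD distribution
#'
#' @param dist A `ppd_distribution`.
#' @return A single number.
#' @export
ppd_mean <- function(dist) {
  stopifnot(inherits(dist, "ppd_distribution"))
  sum(dist$support * dist$mass)
}

#' @rdname ppd_mean
#' @export
ppd_variance <- function(dist) {
  stopifnot(inherits(dist, "ppd_distribution"))
  mu <- sum(dist$support * dist$mass)
  sum(dist$mass * (dist$support - mu)^2)
}

#' Actionability fractions at posterior thresholds
#'
#' Splits a PPD distribution at two clinical decision thresholds: the C1
#' condition (`PPD > tau_pos`, actionably high) and the C2 condition
#' (`PPD < tau_neg`, actionably low). Inequalities are strict.
#'
#' @param dist A [ppd_distribution()].
#' @param tau_pos,tau_neg Thresholds with `0 <= tau_neg < tau_pos <= 1`.
#'   Defaults 0.95 and 0.05.
#' @return An object of class `threshold_report`: list with `tau_pos`,
#'   `tau_neg`, `c1_fraction`, `c2_fraction`, `neither_fraction` (the three
#'   fractions sum to 1).
#' @export
threshold_fractions <- function(dist, tau_pos = 0.95, tau_neg = 0.05) {
  stopifnot(inherits(dist, "ppd_distribution"),
            is.numeric(tau_pos), is.numeric(tau_neg))
  if (!(tau_neg >= 0 && tau_neg < tau_pos && tau_pos <= 1)) {
    stop("thresholds must satisfy 0 <= tau_neg < tau_pos <= 1")
  }
  c1 <- sum(dist$mass[dist$support > tau_pos])
  c2 <- sum(dist$mass[dist$support < tau_neg])
  structure(
    list(tau_pos = tau_pos, tau_neg = tau_neg,
         c1_fraction = c1, c2_fraction = c2,
         neither_fraction = 1 - c1 - c2),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> C1 [PPD>%g]: %.4g  C2 [PPD<%g]: %.4g  neither: %.4g\n",
    x$tau_pos, x$c1_fraction, x$tau_neg, x$c2_fraction, x$neither_fraction))
  invisible(x)
}

#' Sweep the per-locus relative risk of an exchangeable model
#'
#' Recomputes the C1/C2 actionability fractions of an `n`-locus exchangeable
#' model at each relative risk in `rr_grid`.
#'
#' @param n,g0,prior Exchangeable model parameters (see
#'   [exchangeable_model()]).
#' @param rr_grid Ascending vector of relative risks; each must satisfy
#'   `rr * g0 < 1` under the default mapping.
#' @param tau_pos,tau_neg Thresholds for [threshold_fractions()].
#' @param population_mode,mapping Passed through to the model.
#' @return A data frame with columns `rr`, `c1`, `c2`, `neither`.
#' @examples
#' # the highly polygenic architecture swept over GWAS-scale effect sizes
#' sw <- sweep_relative_risk(1000, 0.10, 0.20, seq(1.02, 1.80, by = 0.02))
#' @export
sweep_relative_risk <- function(n, g0, prior, rr_grid,
                                tau_pos = 0.95, tau_neg = 0.05,
                                population_mode = "marginal_independent",
                                mapping = "freq_ratio") {
  stopifnot(is.numeric(rr_grid), length(rr_grid) >= 1L,
            !is.unsorted(rr_grid))
  rows <- lapply(rr_grid, function(rr) {
    m <- exchangeable_model(n, g0, rr, prior,
                            population_mode = population_mode,
                            mapping = mapping)
    tf <- threshold_fractions(ppd_distribution(m), tau_pos, tau_neg)
    data.frame(rr = rr, c1 = tf$c1_fraction, c2 = tf$c2_fraction,
               neither = tf$neither_fraction)
  })
  do.call(rbind, rows)
}

#' Sweep the disease prior of an exchangeable model
#'
#' As [sweep_relative_risk()], but varying the prior probability of disease.
#' Degenerate priors are evaluated in the limit: 0 is replaced by 1e-6 and 1
#' by 1 - 1e-6.
#'
#' @param n,g0,rr Exchangeable model parameters.
#' @param prior_grid Vector of priors in \[0, 1\].
#' @param tau_pos,tau_neg,population_mode,mapping As in
#'   [sweep_relative_risk()].
#' @return A data frame with columns `prior`, `c1`, `c2`, `neither`.
#' @export
sweep_prior <- function(n, g0, rr, prior_grid,
                        tau_pos = 0.95, tau_neg = 0.05,
                        population_mode = "marginal_independent",
                        mapping = "freq_ratio") {
  stopifnot(is.numeric(prior_grid), all(prior_grid >= 0 & prior_grid <= 1))
  rows <- lapply(prior_grid, function(p) {
    p_eff <- min(max(p, 1e-6), 1 - 1e-6)
    m <- exchangeable_model(n, g0, rr, p_eff,
                            population_mode = population_mode,
                            mapping = mapping)
    tf <- threshold_fractions(ppd_distribution(m), tau_pos, tau_neg)
    data.frame(prior = p, c1 = tf$c1_fraction, c2 = tf$c2_fraction,
               neither = tf$neither_fraction)
  })
  do.call(rbind, rows)
}

#' Sweep the number of loci of an exchangeable model
#'
#' Reports the variance of the PPD distribution as the number of loci grows
#' at fixed per-locus frequency and effect.
#'
#' @param g0,rr,prior Exchangeable model parameters.
#' @param n_grid Ascending vector of locus counts.
#' @param population_mode,mapping As in [sweep_relative_risk()].
#' @return A data frame with columns `n` and `ppd_variance`; the full
#'   distributions are attached as the `"distributions"` attribute.
#' @export
sweep_locus_count <- function(g0, rr, prior, n_grid,
                              population_mode = "marginal_independent",
                              mapping = "freq_ratio") {
  stopifnot(is.numeric(n_grid), length(n_grid) >= 1L, !is.unsorted(n_grid))
  dists <- lapply(n_grid, function(n) {
    ppd_distribution(exchangeable_model(n, g0, rr, prior,
                                        population_mode = population_mode,
                                        mapping = mapping))
  })
  out <- data.frame(n = n_grid,
                    ppd_variance = vapply(dists, ppd_variance, numeric(1)))
  attr(out, "distributions") <- dists
  out
}

#' Scaled posterior ratios (SRR)
#'
#' Posterior probabilities of disease for a set of genotype profiles, scaled
#' so the smallest equals exactly 1 — the "fold variation in risk" view of a
#' multilocus panel.
#'
#' @param model A [disease_model()].
#' @param genotypes A matrix of binary genotype profiles (one row per
#'   profile) or a list of vectors.
#' @return Numeric vector of SRR values, minimum exactly 1.
#' @export
scaled_posterior_ratios <- function(model, genotypes) {
  if (is.list(genotypes) && !is.data.frame(genotypes)) {
    genotypes <- do.call(rbind, genotypes)
  }
  if (!is.matrix(genotypes) || nrow(genotypes) == 0L) {
    stop("genotypes must be a non-empty matrix or list of profiles")
  }
  p <- ppd(model, genotypes)
  if (min(p) == 0) stop("smallest posterior is 0; ratios undefined")
  p / min(p)
}
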