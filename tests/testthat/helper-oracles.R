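# Independent brute-force oracles. These never call the distribution engine:
# they enumerate every genotype vector and apply Bayes' rule directly.

# Posterior for one genotype vector by direct Bayes-rule arithmetic.
oracle_ppd <- function(prior, g0, g1, genotype) {
  like1 <- prod(ifelse(genotype == 1, g1, 1 - g1))
  like0 <- prod(ifelse(genotype == 1, g0, 1 - g0))
  prior * like1 / (prior * like1 + (1 - prior) * like0)
}

# Exhaustive PPD distribution over all 2^n genotype vectors for a model,
# under any population mode. Returns support (ascending), mass, and the
# genotype-combination count per support point.
oracle_ppd_distribution <- function(model, mode = model$population_mode) {
  l <- model$loci
  n <- nrow(l)
  stopifnot(n <= 12)
  combos <- as.matrix(expand.grid(rep(list(0:1), n)))
  pvec <- apply(combos, 1L, function(g) oracle_ppd(model$prior, l$g0, l$g1, g))
  carrier <- switch(mode,
    control = l$g0,
    marginal_independent = model$prior * l$g1 + (1 - model$prior) * l$g0,
    mixture = NULL)
  prob_for <- function(p) {
    apply(combos, 1L, function(g) prod(ifelse(g == 1, p, 1 - p)))
  }
  prob <- if (mode == "mixture") {
    model$prior * prob_for(l$g1) + (1 - model$prior) * prob_for(l$g0)
  } else {
    prob_for(carrier)
  }
  key <- factor(signif(pvec, 12))
  mass <- rowsum(prob, key, reorder = TRUE)[, 1]
  count <- rowsum(rep(1, length(pvec)), key, reorder = TRUE)[, 1]
  support <- as.numeric(levels(key))
  o <- order(support)
  list(support = support[o], mass = as.numeric(mass)[o],
       count = as.numeric(count)[o])
}

# Total variation distance between an engine distribution and an oracle one,
# matching support points to 1e-9.
tv_distance <- function(dist, oracle) {
  stopifnot(length(dist$support) == length(oracle$support))
  stopifnot(max(abs(dist$support - oracle$support)) < 1e-9)
  0.5 * sum(abs(dist$mass - oracle$mass))
}

# Random heterogeneous model for property-style loops.
random_model <- function(n, seed, prior = NULL,
                         mode = "marginal_independent") {
  set.seed(seed)
  if (is.null(prior)) prior <- runif(1, 0.05, 0.6)
  g0 <- runif(n, 0.01, 0.4)
  rr <- runif(n, 0.4, 1 / max(g0) * 0.9)
  loci <- mapply(locus_effect, g0 = g0, rr = rr,
                 locus_id = paste0("x", seq_len(n)), SIMPLIFY = FALSE)
  disease_model(loci, prior, mode)
}

# Trapezoidal area under an ROC data frame.
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}
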