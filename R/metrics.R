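# Prognostic-utility metrics: ROC/AUC, predictive values, net
# reclassification improvement, and Kullback-Leibler divergence between
# posterior and prior disease probabilities.

#' Discrete score distribution
#'
#' A probability mass function over score values, used to compute exact
#' (population-level) AUC and ROC curves from analytic PPD distributions
#' rather than finite samples.
#'
#' @param support Score values.
#' @param mass Matching probabilities, summing to 1 (tolerance 1e-9).
#' @return An object of class `score_distribution`.
#' @export
score_distribution <- function(support, mass) {
  stopifnot(is.numeric(support), is.numeric(mass),
            length(support) == length(mass), length(support) >= 1L)
  if (any(mass < 0)) stop("mass entries must be nonnegative")
  if (abs(sum(mass) - 1) > 1e-9) stop("mass must sum to 1")
  o <- order(support)
  structure(list(support = support[o], mass = mass[o]),
            class = "score_distribution")
}

.as_score_dist <- function(x) {
  if (inherits(x, "score_distribution")) return(x)
  if (inherits(x, "ppd_distribution")) {
    return(score_distribution(x$support, x$mass))
  }
  if (is.numeric(x)) {
    tab <- rowsum(rep(1 / length(x), length(x)), factor(x), reorder = TRUE)
    return(score_distribution(as.numeric(rownames(tab)), tab[, 1]))
  }
  stop("cannot interpret scores of class ", paste(class(x), collapse = "/"))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties weighted one half:
#' `AUC = P(S_case > S_control) + 0.5 P(S_case = S_control)`.
#' For two numeric score vectors this is the Mann-Whitney statistic; for
#' [score_distribution()] or [ppd_distribution()] inputs it is computed
#' exactly from the mass functions.
#'
#' @param cases Scores of the case class: numeric vector,
#'   `score_distribution`, or `ppd_distribution`.
#' @param controls Scores of the control class, same options.
#' @return A value in \[0, 1\]; 0.5 for a non-informative score.
#' @examples
#' auc(score_distribution(0:1, c(0.2, 0.8)),
#'     score_distribution(0:1, c(0.6, 0.4)))  # 0.70
#' @export
auc <- function(cases, controls) {
  if (is.numeric(cases) && is.numeric(controls)) {
    m <- length(cases); n <- length(controls)
    if (m == 0L || n == 0L) stop("both classes must be non-empty")
    r <- rank(c(cases, controls))
    return((sum(r[seq_len(m)]) - m * (m + 1) / 2) / (as.numeric(m) * n))
  }
  dc <- .as_score_dist(cases)
  dn <- .as_score_dist(controls)
  # P(case > control) + 0.5 P(equal), via the control cdf at case support
  below <- c(0, cumsum(dn$mass))  # P(control < s) just before each index
  idx_lt <- findInterval(dc$support, dn$support, left.open = TRUE)
  idx_le <- findInterval(dc$support, dn$support)
  p_lt <- below[idx_lt + 1L]
  p_eq <- below[idx_le + 1L] - p_lt
  sum(dc$mass * (p_lt + 0.5 * p_eq))
}

#' ROC curve
#'
#' Operating points (1 - specificity, sensitivity) obtained by calling a
#' score positive when it strictly exceeds a threshold, swept over
#' `thresholds`. Endpoints (0, 0) and (1, 1) are always included, and
#' trapezoidal integration of the returned curve equals [auc()].
#'
#' @inheritParams auc
#' @param thresholds Thresholds to sweep; defaults to all distinct score
#'   values of both classes.
#' @return A data frame with columns `fpr` and `tpr`, non-decreasing in both.
#' @export
roc_curve <- function(cases, controls, thresholds = NULL) {
  dc <- .as_score_dist(cases)
  dn <- .as_score_dist(controls)
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(dc$support, dn$support)))
  }
  thresholds <- sort(thresholds)
  surv <- function(d, t) {  # P(score > t)
    vapply(t, function(ti) sum(d$mass[d$support > ti]), numeric(1))
  }
  tpr <- c(1, surv(dc, thresholds), 0)
  fpr <- c(1, surv(dn, thresholds), 0)
  out <- data.frame(fpr = rev(fpr), tpr = rev(tpr))
  unique(out)
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Positive and negative predictive values by Bayes' rule, and their simple
#' average as a single prevalence-aware utility summary.
#'
#' @param sensitivity,specificity,prevalence Probabilities in \[0, 1\].
#' @return List with `ppv`, `npv`, `average`. A zero denominator (no positive
#'   or no negative calls possible) yields `NA` for the affected value with a
#'   warning naming it.
#' @examples
#' predictive_values(0.9, 0.8, 0.2)  # ppv 0.5294, npv 0.9697
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  d_pos <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  d_neg <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  ppv <- if (d_pos > 0) sensitivity * prevalence / d_pos else {
    warning("PPV undefined: no positive results at these parameters")
    NA_real_
  }
  npv <- if (d_neg > 0) specificity * (1 - prevalence) / d_neg else {
    warning("NPV undefined: no negative results at these parameters")
    NA_real_
  }
  list(ppv = ppv, npv = npv, average = (ppv + npv) / 2)
}

#' Kullback-Leibler divergence of posterior from prior disease probability
#'
#' Measures how far genotype information moves posterior disease
#' probabilities away from the prior, across the population the model is
#' applied to. Two variants are computed (natural log, nats):
#'
#' * `"weighted"` (default): the population-expected Bernoulli KL,
#'   `sum_g P(g) * [ p_g ln(p_g / K) + (1 - p_g) ln((1 - p_g)/(1 - K)) ]`
#'   with `p_g` the posterior for genotype combination `g` and `K` the
#'   prior. Nonnegative, and zero exactly when every posterior equals the
#'   prior.
#' * `"literal"`: the unweighted disease-term sum
#'   `sum_g p_g ln(p_g / K)` over all multilocus genotype combinations.
#'   This needs the number of genotype combinations behind each support
#'   point, which grid-binned heterogeneous distributions do not carry
#'   (`NA` with a warning there).
#'
#' @param dist A [ppd_distribution()].
#' @param prior Prior probability in (0, 1); defaults to the distribution's.
#' @param variant `"weighted"` or `"literal"`.
#' @return A single value in nats.
#' @export
kl_divergence <- function(dist, prior = NULL,
                          variant = c("weighted", "literal")) {
  stopifnot(inherits(dist, "ppd_distribution"))
  variant <- match.arg(variant)
  if (is.null(prior)) prior <- dist$prior
  if (prior <= 0 || prior >= 1) stop("prior must lie strictly in (0, 1)")
  p <- dist$support
  if (variant == "weighted") {
    term <- function(q, ref) ifelse(q == 0, 0, q * log(q / ref))
    return(sum(dist$mass * (term(p, prior) + term(1 - p, 1 - prior))))
  }
  if (anyNA(dist$combinations)) {
    warning("literal KL needs genotype-combination counts; ",
            "unavailable for grid-binned distributions")
    return(NA_real_)
  }
  sum(dist$combinations * ifelse(p == 0, 0, p * log(p / prior)))
}

#' Net reclassification improvement
#'
#' Net proportion of events moved to a higher risk category minus the net
#' proportion of non-events moved up, when subjects are reassigned from
#' `old_category` to `new_category`:
#' `NRI = [P(up|event) - P(down|event)] - [P(up|non-event) - P(down|non-event)]`.
#'
#' @param old_category,new_category Ordinal risk categories (numeric or
#'   ordered factor), one per subject.
#' @param labels Binary event indicator (0/1, logical, or two-level factor).
#' @return A value in \[-2, 2\].
#' @export
nri <- function(old_category, new_category, labels) {
  old_category <- as.numeric(old_category)
  new_category <- as.numeric(new_category)
  lab <- .as_binary01(labels)
  stopifnot(length(old_category) == length(new_category),
            length(old_category) == length(lab))
  if (sum(lab == 1) == 0L) stop("no events in labels")
  if (sum(lab == 0) == 0L) stop("no non-events in labels")
  up <- new_category > old_category
  down <- new_category < old_category
  (mean(up[lab == 1]) - mean(down[lab == 1])) -
    (mean(up[lab == 0]) - mean(down[lab == 0]))
}

.as_binary01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels factor must have two levels")
    return(as.integer(labels) - 1L)
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  stop("labels must be logical, 0/1 numeric, or a two-level factor")
}
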