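# Genetic risk scores, quantile stratification, and calibration of
# case-control intercepts to population prevalence.

#' Genetic risk score
#'
#' Weighted sum of risk-allele counts, `GRS = sum_i w_i R_i`, with `R_i` the
#' number of risk alleles (0, 1 or 2) at locus `i`. Unweighted scores set all
#' weights to 1, treating every risk locus equally.
#'
#' @param counts Integer risk-allele counts in \{0, 1, 2\}: a vector (one
#'   subject) or a matrix with one row per subject.
#' @param weights Per-locus weights; `NULL` (default) for the unweighted
#'   score.
#' @return A score per subject.
#' @examples
#' grs(c(2, 1, 0), weights = c(0.5, 0.2, 0.1))  # 1.2
#' grs(c(2, 2, 1))                              # 5
#' @export
grs <- function(counts, weights = NULL) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  if (!all(counts %in% c(0L, 1L, 2L))) {
    stop("risk-allele counts must be 0, 1 or 2")
  }
  if (is.null(weights)) weights <- rep(1, ncol(counts))
  stopifnot(is.numeric(weights), all(is.finite(weights)))
  if (length(weights) != ncol(counts)) {
    stop("got ", length(weights), " weights for ", ncol(counts), " loci")
  }
  as.numeric(counts %*% weights)
}

#' Quantile bins of a score
#'
#' Partitions scores into `q` ordered bins of near-equal size (quintiles by
#' default). Sizes differ by at most one, with the remainder spread over the
#' lower bins; tied scores keep their input order (stable sort), so the
#' partition is deterministic. Bin 1 holds the lowest scores.
#'
#' @param scores Numeric vector.
#' @param q Number of bins, >= 2.
#' @return Integer bin index (1..q) per score, in input order.
#' @export
quantile_bins <- function(scores, q = 5L) {
  stopifnot(is.numeric(scores), q >= 2L, q == as.integer(q))
  n <- length(scores)
  if (length(unique(scores)) < q) {
    stop("need at least ", q, " distinct scores, got ",
         length(unique(scores)))
  }
  sizes <- rep(n %/% q, q) + (seq_len(q) <= n %% q)
  bins <- integer(n)
  bins[order(scores)] <- rep(seq_len(q), sizes)
  bins
}

#' Fold-risk across score bins
#'
#' Disease risk (cumulative incidence, cases/total) in each bin divided by
#' the risk in a reference bin — e.g. the "top versus bottom quintile"
#' fold-increase in risk. Counts are combined before any division. An
#' odds-ratio version is available via `measure = "odds"`.
#'
#' @param bins Integer bin index per subject (see [quantile_bins()]).
#' @param labels Binary disease indicator per subject.
#' @param reference_bin Bin used as denominator (default 1, the lowest).
#' @param measure `"risk"` (default) for risk ratios, `"odds"` for odds
#'   ratios.
#' @return Data frame with columns `bin`, `n`, `cases`, `risk`, `ratio`.
#' @export
bin_risk_ratios <- function(bins, labels, reference_bin = 1L,
                            measure = c("risk", "odds")) {
  measure <- match.arg(measure)
  lab <- .as_binary01(labels)
  stopifnot(length(bins) == length(lab))
  ids <- sort(unique(bins))
  if (!reference_bin %in% ids) stop("reference_bin ", reference_bin,
                                    " not present")
  n <- vapply(ids, function(b) sum(bins == b), numeric(1))
  cases <- vapply(ids, function(b) sum(lab[bins == b]), numeric(1))
  if (any(n == 0)) stop("empty bin")
  ref <- which(ids == reference_bin)
  if (cases[ref] == 0) stop("reference bin has zero cases; ratio undefined")
  ratio <- if (measure == "risk") {
    (cases * n[ref]) / (n * cases[ref])
  } else {
    if (cases[ref] == n[ref]) stop("reference bin has zero controls")
    (cases * (n[ref] - cases[ref])) / ((n - cases) * cases[ref])
  }
  data.frame(bin = ids, n = n, cases = cases, risk = cases / n,
             ratio = ratio)
}

#' Calibrate a case-control intercept to population prevalence
#'
#' A logistic model fitted to a case-control sample has its intercept offset
#' by the log case:control sampling ratio. Replacing that offset with the
#' log odds of the population prevalence gives the intercept valid in the
#' target population:
#' `beta0_pop = beta0_cc - ln(n_case/n_control) + ln(prev/(1 - prev))`.
#'
#' @param beta0_cc Intercept from the case-control fit.
#' @param n_case,n_control Sample sizes used in the fit.
#' @param prevalence Population disease prevalence in (0, 1).
#' @return The calibrated intercept.
#' @examples
#' calibrate_intercept(0, 500, 500, 0.2)  # log(0.25)
#' @export
calibrate_intercept <- function(beta0_cc, n_case, n_control, prevalence) {
  stopifnot(is.numeric(beta0_cc), length(beta0_cc) == 1L,
            n_case >= 1, n_control >= 1)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly in (0, 1)")
  }
  beta0_cc - log(n_case / n_control) + log(prevalence / (1 - prevalence))
}
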