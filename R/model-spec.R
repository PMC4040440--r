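# Genetic architecture specification: per-locus effects and disease models.
#
# A locus is summarised by the frequency of its predisposing (risk-increasing)
# genotype in controls (g0) and its relative risk (rr); the case frequency g1
# and the carrier / non-carrier likelihood ratios follow from the chosen
# rr -> g1 mapping. All frequencies are proportions, never percents.

#' Construct a single susceptibility locus
#'
#' Defines one disease-susceptibility locus by the frequency of its
#' predisposing genotype in controls and its relative risk, deriving the case
#' frequency and the carrier/non-carrier likelihood ratios used by the
#' posterior-probability engine.
#'
#' Two mappings from relative risk to the case frequency `g1` are offered.
#' The default, `"freq_ratio"`, sets `g1 = rr * g0`, so that `rr` equals the
#' carrier likelihood ratio `g1 / g0` exactly. The `"epidemiological"`
#' mapping instead solves the prevalence-consistent system in which carriers
#' have `rr` times the disease probability of non-carriers at a stated
#' disease prior, by fixed-point iteration to relative tolerance 1e-12.
#'
#' @param g0 Frequency of the predisposing genotype in controls, in (0, 1).
#' @param rr Relative risk of the predisposing genotype, positive.
#' @param locus_id Optional identifier; defaults to `"locus"`.
#' @param weight Optional genetic-risk-score weight for this locus.
#' @param mapping `"freq_ratio"` (default) or `"epidemiological"`.
#' @param prior Disease prior, required (in (0, 1)) for the
#'   `"epidemiological"` mapping; ignored otherwise.
#' @return An object of class `locus_effect`: a list with elements
#'   `locus_id`, `g0`, `rr`, `weight`, `g1`, `lr_pos` (carrier likelihood
#'   ratio `g1/g0`) and `lr_neg` (non-carrier ratio `(1-g1)/(1-g0)`).
#' @examples
#' locus_effect(g0 = 0.05, rr = 2)        # g1 = 0.10, lr_pos = 2
#' locus_effect(0.10, 1.45)$g1            # 0.145
#' @export
locus_effect <- function(g0, rr, locus_id = "locus", weight = NA_real_,
                         mapping = c("freq_ratio", "epidemiological"),
                         prior = NULL) {
  mapping <- match.arg(mapping)
  stopifnot(is.numeric(g0), length(g0) == 1L, is.finite(g0),
            is.numeric(rr), length(rr) == 1L, is.finite(rr))
  if (g0 <= 0 || g0 >= 1) stop("g0 must lie strictly in (0, 1), got ", g0)
  if (rr <= 0) stop("rr must be positive, got ", rr)

  if (mapping == "freq_ratio") {
    if (rr * g0 >= 1) {
      stop("freq_ratio mapping requires rr * g0 < 1 (got ", rr * g0, ")")
    }
    g1 <- rr * g0
  } else {
    if (is.null(prior) || prior <= 0 || prior >= 1) {
      stop("epidemiological mapping requires a prior strictly in (0, 1)")
    }
    g1 <- .g1_epidemiological(g0, rr, prior)
  }

  structure(
    list(locus_id = as.character(locus_id), g0 = g0, rr = rr,
         weight = as.numeric(weight), g1 = g1,
         lr_pos = g1 / g0, lr_neg = (1 - g1) / (1 - g0)),
    class = "locus_effect"
  )
}

# Solve for g1 under the epidemiological mapping: carriers have rr times the
# disease risk of non-carriers, the population prevalence equals `prior`, and
# the control carrier frequency equals g0. Unknowns: population carrier
# frequency g and the non-carrier penetrance p0.
.g1_epidemiological <- function(g0, rr, prior, tol = 1e-12,
                                max_iter = 10000L) {
  g <- g0
  for (iter in seq_len(max_iter)) {
    p0 <- prior / (1 + g * (rr - 1))  # from prior = g*rr*p0 + (1-g)*p0
    p1 <- rr * p0
    if (p1 >= 1) stop("epidemiological mapping infeasible: carrier risk >= 1")
    g_new <- g0 * (1 - prior) / (1 - p1)
    if (g_new <= 0 || g_new >= 1) {
      stop("epidemiological mapping infeasible for g0=", g0, ", rr=", rr,
           ", prior=", prior)
    }
    if (abs(g_new - g) <= tol * max(g, .Machine$double.eps)) {
      g1 <- g_new * p1 / prior
      if (g1 <= 0 || g1 >= 1) stop("derived g1 outside (0, 1)")
      return(g1)
    }
    g <- g_new
  }
  stop("epidemiological mapping did not converge after ", max_iter,
       " iterations")
}

#' @export
print.locus_effect <- function(x, ...) {
  cat(sprintf("<locus_effect %s> g0=%g rr=%g g1=%g lr+=%g lr-=%g\n",
              x$locus_id, x$g0, x$rr, x$g1, x$lr_pos, x$lr_neg))
  invisible(x)
}

#' Population frequency of the predisposing genotype
#'
#' Marginal frequency of the predisposing genotype in a population with
#' disease prior `prior`: `g_pop = prior * g1 + (1 - prior) * g0`.
#'
#' @param locus A `locus_effect`.
#' @param prior Disease prior in \[0, 1\].
#' @return A proportion. `prior = 0` gives `g0`; `prior = 1` gives `g1`.
#' @export
population_frequency <- function(locus, prior) {
  stopifnot(inherits(locus, "locus_effect"),
            is.numeric(prior), length(prior) == 1L,
            prior >= 0, prior <= 1)
  prior * locus$g1 + (1 - prior) * locus$g0
}

#' Assemble a multilocus disease model
#'
#' Bundles a disease prior with a set of susceptibility loci and the
#' population over which posterior-probability distributions are taken.
#'
#' The `population_mode` names the genotype distribution the engine
#' integrates over: `"marginal_independent"` draws each locus independently
#' at its marginal population frequency `g_pop`; `"mixture"` is the exact
#' generative population (a `prior`-weighted mixture of the case and control
#' genotype distributions); `"control"` uses control frequencies only.
#'
#' @param loci A list of [locus_effect()] objects, or a data frame with
#'   columns `locus_id`, `g0`, `rr` and optionally `weight` (then built with
#'   the `freq_ratio` mapping).
#' @param prior Prior probability of disease, in \[0, 1\].
#' @param population_mode One of `"marginal_independent"` (default),
#'   `"mixture"`, `"control"`.
#' @return An object of class `disease_model` with elements `prior`, `loci`
#'   (a data frame, one row per locus), `population_mode`, and an
#'   `exchangeable` flag (TRUE when all loci share g0 and rr).
#' @seealso [exchangeable_model()] for the identical-loci shortcut.
#' @export
disease_model <- function(loci, prior,
                          population_mode = c("marginal_independent",
                                              "mixture", "control")) {
  population_mode <- match.arg(population_mode)
  stopifnot(is.numeric(prior), length(prior) == 1L, is.finite(prior))
  if (prior < 0 || prior > 1) stop("prior must lie in [0, 1]")

  if (is.data.frame(loci)) {
    req <- c("locus_id", "g0", "rr")
    if (!all(req %in% names(loci))) {
      stop("loci data frame needs columns: ", paste(req, collapse = ", "))
    }
    w <- if ("weight" %in% names(loci)) loci$weight else NA_real_
    loci <- mapply(locus_effect, g0 = loci$g0, rr = loci$rr,
                   locus_id = loci$locus_id, weight = w,
                   SIMPLIFY = FALSE)
  }
  if (!is.list(loci) || length(loci) == 0L ||
      !all(vapply(loci, inherits, logical(1), "locus_effect"))) {
    stop("loci must be a non-empty list of locus_effect objects")
  }
  tab <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus_id = l$locus_id, g0 = l$g0, rr = l$rr,
               weight = l$weight, g1 = l$g1, lr_pos = l$lr_pos,
               lr_neg = l$lr_neg, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(tab$locus_id)) {
    stop("duplicate locus ids: ",
         paste(unique(tab$locus_id[duplicated(tab$locus_id)]),
               collapse = ", "))
  }
  exch <- nrow(tab) == 1L ||
    (length(unique(tab$g0)) == 1L && length(unique(tab$rr)) == 1L &&
     length(unique(tab$g1)) == 1L)

  structure(
    list(prior = prior, loci = tab, population_mode = population_mode,
         exchangeable = exch),
    class = "disease_model"
  )
}

#' Exchangeable disease model (identical loci)
#'
#' Shortcut for architectures in which all `n` loci share one control
#' frequency and one relative risk, so the posterior probability of disease
#' depends only on the number of predisposing genotypes carried. The PPD
#' engine exploits this with carrier-count (binomial) arithmetic, making
#' models with thousands of loci exact and fast.
#'
#' @param n Number of loci, >= 1.
#' @param g0,rr Shared control frequency and relative risk (see
#'   [locus_effect()]).
#' @param prior Prior probability of disease.
#' @param population_mode Passed to [disease_model()].
#' @param mapping,weight Passed to [locus_effect()].
#' @return A `disease_model` with `exchangeable = TRUE`.
#' @examples
#' # the highly polygenic architecture: 1000 common loci of small effect
#' m <- exchangeable_model(n = 1000, g0 = 0.10, rr = 1.45, prior = 0.20)
#' @export
exchangeable_model <- function(n, g0, rr, prior,
                               population_mode = c("marginal_independent",
                                                   "mixture", "control"),
                               mapping = c("freq_ratio", "epidemiological"),
                               weight = NA_real_) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == as.integer(n))
  population_mode <- match.arg(population_mode)
  mapping <- match.arg(mapping)
  proto <- locus_effect(g0, rr, locus_id = "L1", weight = weight,
                        mapping = mapping, prior = prior)
  loci <- lapply(seq_len(n), function(i) {
    l <- proto
    l$locus_id <- paste0("L", i)
    l
  })
  m <- disease_model(loci, prior, population_mode)
  m$exchangeable <- TRUE
  m
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf(
    "<disease_model> %d loci, prior=%g, population_mode=%s%s\n",
    nrow(x$loci), x$prior, x$population_mode,
    if (x$exchangeable) " (exchangeable)" else ""))
  invisible(x)
}

# Compact description used to stamp distributions and output files.
.model_digest <- function(model) {
  l <- model$loci
  if (model$exchangeable) {
    sprintf("n=%d;g0=%.17g;rr=%.17g;prior=%.17g", nrow(l), l$g0[1], l$rr[1],
            model$prior)
  } else {
    sprintf("n=%d;prior=%.17g;g0sum=%.17g;rrsum=%.17g", nrow(l), model$prior,
            sum(l$g0), sum(l$rr))
  }
}

# Per-locus carrier probability under a population mode.
.carrier_prob <- function(model, mode = model$population_mode) {
  l <- model$loci
  switch(mode,
         control = l$g0,
         marginal_independent = model$prior * l$g1 + (1 - model$prior) * l$g0,
         mixture = stop("mixture mode has no single carrier probability"),
         stop("unknown population mode: ", mode))
}
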