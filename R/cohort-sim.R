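# Seeded cohort simulator. Generates genotype cohorts with exactly the
# statistical structure the Naive Bayes machinery assumes: a disease label
# drawn from the prior, then conditionally independent loci given the label.

# Run code under a temporary RNG state so simulation never disturbs the
# caller's random stream. Mersenne-Twister via set.seed(); the generator
# identity is recorded in cohort provenance.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.sim_provenance <- function(seed, design, model_digest, sizes) {
  list(seed = as.integer(seed), rng = "Mersenne-Twister",
       design = design, model = model_digest, sizes = sizes,
       package = "polyrisk",
       version = as.character(utils::packageVersion("polyrisk")))
}

# Binary carrier matrix for labelled subjects under a disease model.
.draw_genotypes <- function(model, disease) {
  n <- length(disease)
  l <- model$loci
  g <- matrix(0L, n, nrow(l), dimnames = list(NULL, l$locus_id))
  for (j in seq_len(nrow(l))) {
    p <- ifelse(disease == 1L, l$g1[j], l$g0[j])
    g[, j] <- stats::rbinom(n, 1L, p)
  }
  g
}

#' Simulate a population cohort under a disease model
#'
#' Draws each subject's disease label from the model prior, then each locus
#' carrier state conditionally on the label (`Bernoulli(g1)` for cases,
#' `Bernoulli(g0)` for controls). Identical seeds reproduce identical
#' cohorts; the seed and generator are recorded in the cohort provenance.
#'
#' @param model A [disease_model()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A [cohort()] with labels `control`/`case`.
#' @export
simulate_population <- function(model, n, seed) {
  stopifnot(inherits(model, "disease_model"), n >= 1)
  .with_seed(seed, {
    d <- stats::rbinom(n, 1L, model$prior)
    g <- .draw_genotypes(model, d)
  })
  cohort(g, factor(ifelse(d == 1L, "case", "control"),
                   levels = c("control", "case")),
         provenance = .sim_provenance(seed, "population",
                                      .model_digest(model), c(n = n)))
}

#' Simulate a case-control cohort under a disease model
#'
#' Fixed numbers of cases and controls, genotypes drawn from the
#' class-conditional carrier frequencies. The intended consumers are the
#' classifier and the intercept-calibration workflow, where the sampling
#' ratio differs from the population prevalence by design.
#'
#' @param model A [disease_model()].
#' @param n_case,n_control Class sizes, >= 1.
#' @param seed Integer seed.
#' @return A [cohort()] with labels `control`/`case` (controls first).
#' @export
simulate_case_control <- function(model, n_case, n_control, seed) {
  stopifnot(inherits(model, "disease_model"), n_case >= 1, n_control >= 1)
  d <- c(rep(0L, n_control), rep(1L, n_case))
  .with_seed(seed, g <- .draw_genotypes(model, d))
  cohort(g, factor(ifelse(d == 1L, "case", "control"),
                   levels = c("control", "case")),
         provenance = .sim_provenance(seed, "case_control",
                                      .model_digest(model),
                                      c(n_case = n_case,
                                        n_control = n_control)))
}

#' Simulate a multi-class cohort from a class table
#'
#' Draws genotype states per locus from the class-conditional categorical
#' frequencies of a [class_table()] — the generative counterpart of
#' [nb_fit()], used e.g. to emulate a multi-disease classification design.
#'
#' @param table A [class_table()].
#' @param class_sizes Named vector of subjects per class (names must match
#'   the table's classes), each >= 1.
#' @param seed Integer seed.
#' @return A [cohort()].
#' @export
simulate_multiclass <- function(table, class_sizes, seed) {
  stopifnot(inherits(table, "class_table"))
  if (is.null(names(class_sizes)) ||
      !setequal(names(class_sizes), table$classes)) {
    stop("class_sizes must be named by the table's classes")
  }
  class_sizes <- class_sizes[table$classes]
  if (any(class_sizes < 1)) stop("every class size must be >= 1")
  lab <- factor(rep(table$classes, class_sizes), levels = table$classes)
  n <- length(lab)
  g <- matrix(NA_character_, n, length(table$loci),
              dimnames = list(NULL, table$loci))
  .with_seed(seed, {
    for (loc in table$loci) {
      f <- table$freq[[loc]]
      for (cl in table$classes) {
        idx <- which(lab == cl)
        g[idx, loc] <- sample(rownames(f), length(idx), replace = TRUE,
                              prob = f[, cl])
      }
    }
  })
  # keep integer states integer so cohorts round-trip through files cleanly
  if (all(!is.na(suppressWarnings(as.integer(g))))) {
    g <- matrix(as.integer(g), n, ncol(g), dimnames = dimnames(g))
  }
  cohort(g, lab,
         provenance = .sim_provenance(seed, "multiclass",
                                      paste0("class_table:",
                                             length(table$loci), "loci"),
                                      class_sizes))
}
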