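# Categorical Naive Bayes genotype classifier for binary or multi-class
# disease labels, with stratified k-fold cross-validation.

#' Cohort container
#'
#' A genotype matrix with class labels and generation provenance — the
#' common currency of the simulator, the classifier and the file I/O.
#'
#' @param genotypes Matrix of categorical genotype states (commonly 0/1/2),
#'   one row per subject, one column per locus; `NA` marks missing calls.
#' @param labels Class label per subject (coerced to factor).
#' @param subjects Optional subject ids; defaults to `S1..Sn`.
#' @param provenance Named list recording how the cohort was made (seed,
#'   generating model, source file, ...).
#' @return An object of class `cohort`.
#' @export
cohort <- function(genotypes, labels, subjects = NULL, provenance = list()) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  labels <- as.factor(labels)
  if (length(labels) != nrow(genotypes)) {
    stop("labels length does not match genotype rows")
  }
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("L", seq_len(ncol(genotypes)))
  }
  structure(list(subjects = as.character(subjects), genotypes = genotypes,
                 labels = labels, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d loci; classes: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(sprintf("%s=%d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Class-conditional genotype frequency table
#'
#' Constructs a classifier parameter table directly (for simulation or
#' hand-specified models). Each locus carries one column of state
#' frequencies per class.
#'
#' @param freq Named list, one element per locus: a matrix with one row per
#'   genotype state (rownames = state labels) and one column per class
#'   (colnames = class labels); columns sum to 1.
#' @param priors Class prior probabilities, named by class, summing to 1.
#' @param pseudocount Smoothing pseudocount recorded with the table
#'   (informational when built by hand).
#' @return An object of class `class_table`.
#' @export
class_table <- function(freq, priors, pseudocount = 0) {
  stopifnot(is.list(freq), length(freq) >= 1L)
  classes <- names(priors)
  if (is.null(classes)) stop("priors must be named by class")
  if (abs(sum(priors) - 1) > 1e-9) stop("priors must sum to 1")
  for (nm in names(freq)) {
    f <- freq[[nm]]
    if (!is.matrix(f) || is.null(rownames(f)) || is.null(colnames(f))) {
      stop("freq[['", nm, "']] must be a matrix with state rownames and ",
           "class colnames")
    }
    if (!setequal(colnames(f), classes)) {
      stop("freq[['", nm, "']] classes do not match priors")
    }
    if (any(abs(colSums(f) - 1) > 1e-9)) {
      stop("freq[['", nm, "']] columns must each sum to 1")
    }
    freq[[nm]] <- f[, classes, drop = FALSE]
  }
  structure(list(classes = classes, priors = as.numeric(priors),
                 freq = freq, loci = names(freq),
                 pseudocount = pseudocount),
            class = "class_table")
}

#' Fit a Naive Bayes genotype classifier
#'
#' Estimates class priors and per-locus, per-class categorical genotype-state
#' frequencies from a labelled cohort, with additive smoothing:
#' `(count + pseudocount) / (class_n + pseudocount * n_states)`. Missing
#' genotypes are excluded from the counts of their locus. A locus with no
#' observed genotypes in some class is dropped with a warning.
#'
#' @param x A [cohort()].
#' @param pseudocount Nonnegative smoothing constant added per state
#'   (default 0.5, a Jeffreys-style prior).
#' @param priors Optional named class priors overriding the observed class
#'   proportions.
#' @return A [class_table()].
#' @export
nb_fit <- function(x, pseudocount = 0.5, priors = NULL) {
  stopifnot(inherits(x, "cohort"), pseudocount >= 0)
  classes <- levels(x$labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_by_class <- tabulate(x$labels, nbins = length(classes))
  if (any(n_by_class == 0L)) {
    stop("class with zero subjects: ",
         paste(classes[n_by_class == 0L], collapse = ", "))
  }
  if (is.null(priors)) {
    priors <- stats::setNames(n_by_class / sum(n_by_class), classes)
  } else {
    if (!setequal(names(priors), classes)) stop("priors must name all classes")
    priors <- priors[classes] / sum(priors)
  }
  freq <- list()
  dropped <- character()
  for (j in seq_len(ncol(x$genotypes))) {
    g <- x$genotypes[, j]
    states <- sort(unique(g[!is.na(g)]))
    if (length(states) == 0L) { dropped <- c(dropped, colnames(x$genotypes)[j]); next }
    counts <- vapply(classes, function(cl) {
      gc <- g[x$labels == cl & !is.na(g)]
      vapply(states, function(s) sum(gc == s), numeric(1))
    }, numeric(length(states)))
    counts <- matrix(counts, nrow = length(states),
                     dimnames = list(as.character(states), classes))
    if (any(colSums(counts) == 0)) {
      dropped <- c(dropped, colnames(x$genotypes)[j])
      next
    }
    f <- sweep(counts + pseudocount, 2,
               colSums(counts) + pseudocount * length(states), "/")
    freq[[colnames(x$genotypes)[j]]] <- f
  }
  if (length(dropped) > 0L) {
    warning("dropped loci with no usable genotypes in some class: ",
            paste(dropped, collapse = ", "))
  }
  if (length(freq) == 0L) stop("no usable loci")
  class_table(freq, priors, pseudocount = pseudocount)
}

#' Posterior class probabilities under a Naive Bayes table
#'
#' For each subject, posteriors proportional to
#' `prior_c * prod_i P(g_i | c)` over the table's loci, accumulated in log
#' space and normalised. Missing genotypes contribute no factor (their locus
#' is skipped). A genotype state absent from the fitted table is an error
#' when the table was fitted without smoothing, since its likelihood is
#' undefined rather than zero.
#'
#' @param table A [class_table()].
#' @param genotypes Matrix (subjects x loci, column names matching the
#'   table's loci) or a single profile vector.
#' @return Matrix of posterior probabilities, one row per subject, one
#'   column per class; rows sum to 1.
#' @export
nb_predict <- function(table, genotypes) {
  stopifnot(inherits(table, "class_table"))
  if (!is.matrix(genotypes)) {
    genotypes <- matrix(genotypes, nrow = 1L,
                        dimnames = list(NULL, table$loci))
  }
  miss <- setdiff(table$loci, colnames(genotypes))
  if (length(miss) > 0L) {
    stop("genotype matrix lacks loci: ", paste(miss, collapse = ", "))
  }
  k <- length(table$classes)
  loglik <- matrix(rep(log(table$priors), each = nrow(genotypes)),
                   nrow = nrow(genotypes), ncol = k,
                   dimnames = list(NULL, table$classes))
  for (loc in table$loci) {
    f <- table$freq[[loc]]
    g <- as.character(genotypes[, loc])
    seen <- !is.na(g)
    unknown <- seen & !(g %in% rownames(f))
    if (any(unknown)) {
      stop("genotype state(s) ", paste(unique(g[unknown]), collapse = ", "),
           " at locus ", loc, " not present in the fitted table")
    }
    idx <- match(g[seen], rownames(f))
    loglik[seen, ] <- loglik[seen, , drop = FALSE] +
      log(f[idx, , drop = FALSE])
  }
  mx <- apply(loglik, 1L, max)
  post <- exp(loglik - mx)
  post / rowSums(post)
}

#' Stratified k-fold cross-validation of the Naive Bayes classifier
#'
#' Splits each class separately into `k` folds (seeded shuffle, so the
#' partition is deterministic), trains on k-1 folds and evaluates on the
#' held-out fold. Accuracy is the proportion of subjects whose top-posterior
#' class is the true class; AUC is macro-averaged over one-vs-rest
#' comparisons using the class posterior as the score, pooled across folds
#' (micro averaging is available).
#'
#' @param x A [cohort()].
#' @param k Number of folds (default 10); every class must have >= k
#'   members.
#' @param seed Integer seed controlling the fold shuffle.
#' @param pseudocount Passed to [nb_fit()].
#' @param average `"macro"` (default) or `"micro"` one-vs-rest AUC
#'   averaging.
#' @return List with `fold_accuracy` (length k), `accuracy` (their mean),
#'   `auc` (averaged one-vs-rest), `per_class_auc`, `folds` (test-fold index
#'   per subject), and `posteriors` (cross-validated posterior matrix).
#' @export
nb_cross_validate <- function(x, k = 10L, seed = 1L, pseudocount = 0.5,
                              average = c("macro", "micro")) {
  stopifnot(inherits(x, "cohort"), k >= 2L)
  average <- match.arg(average)
  n <- nrow(x$genotypes)
  class_n <- tabulate(x$labels, nbins = nlevels(x$labels))
  if (any(class_n < k)) {
    stop("every class needs at least k = ", k, " members; smallest has ",
         min(class_n))
  }
  folds <- integer(n)
  .with_seed(seed, {
    for (cl in levels(x$labels)) {
      idx <- sample(which(x$labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  posteriors <- matrix(NA_real_, n, nlevels(x$labels),
                       dimnames = list(NULL, levels(x$labels)))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    train <- cohort(x$genotypes[!test, , drop = FALSE], x$labels[!test],
                    x$subjects[!test])
    fit <- nb_fit(train, pseudocount = pseudocount)
    post <- nb_predict(fit, x$genotypes[test, , drop = FALSE])
    # loci dropped in a fold leave posteriors on the remaining loci
    posteriors[test, colnames(post)] <- post
    called <- colnames(post)[max.col(post, ties.method = "first")]
    fold_acc[f] <- mean(called == as.character(x$labels[test]))
  }
  per_class <- vapply(levels(x$labels), function(cl) {
    auc(posteriors[x$labels == cl, cl], posteriors[x$labels != cl, cl])
  }, numeric(1))
  auc_avg <- if (average == "macro") mean(per_class) else {
    w <- tabulate(x$labels) / n
    sum(w * per_class)
  }
  list(fold_accuracy = fold_acc, accuracy = mean(fold_acc),
       auc = auc_avg, per_class_auc = per_class, folds = folds,
       posteriors = posteriors)
}
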