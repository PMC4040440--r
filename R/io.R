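# File I/O: model-specification tables and genotype cohorts.
#
# Canonical dialect is TSV (CSV accepted on read), UTF-8, '#' comment lines.
# Writers stamp structured provenance in leading comments; readers recover
# it, so write-then-read is the identity on canonical form. Numbers are
# written at full precision (%.17g).

.detect_sep <- function(path) {
  for (line in readLines(path, n = 50L, warn = FALSE)) {
    if (!startsWith(line, "#") && nzchar(trimws(line))) {
      return(if (grepl("\t", line)) "\t" else ",")
    }
  }
  stop("no data lines found in ", path)
}

# key=value pairs from leading '#' comment lines
.read_header_meta <- function(path) {
  meta <- list()
  for (line in readLines(path, warn = FALSE)) {
    if (!startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$",
                                  line))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

.fmt <- function(x) sprintf("%.17g", x)

#' Read a disease-model specification table
#'
#' Reads a delimited table with one locus per row and columns `locus_id`,
#' `g0` (predisposing-genotype frequency in controls), `rr` (relative risk)
#' and optionally `weight`. Leading `#` comment lines may carry
#' `key = value` metadata; `prior` and `population_mode` found there are
#' used unless overridden by the arguments.
#'
#' @param path File path (TSV; CSV accepted).
#' @param prior Disease prior; required if the file carries none.
#' @param population_mode Population mode; defaults to the file's, else
#'   `"marginal_independent"`.
#' @param percent If `TRUE`, `g0` values in the file are percentages and
#'   are divided by 100.
#' @return A [disease_model()].
#' @seealso [write_model_spec()]
#' @export
read_model_spec <- function(path, prior = NULL, population_mode = NULL,
                            percent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- .read_header_meta(path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = NA)
  req <- c("locus_id", "g0", "rr")
  if (!all(req %in% names(tab))) {
    stop("model spec must have columns locus_id, g0, rr; found: ",
         paste(names(tab), collapse = ", "))
  }
  for (col in intersect(c("g0", "rr", "weight"), names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric ", col, " at data row ", bad[1], ": '",
           tab[[col]][bad[1]], "'")
    }
    tab[[col]] <- v
  }
  if (percent) tab$g0 <- tab$g0 / 100
  if (is.null(prior)) {
    if (is.null(meta$prior)) stop("no prior given and none in file header")
    prior <- as.numeric(meta$prior)
  }
  if (is.null(population_mode)) {
    population_mode <- if (!is.null(meta$population_mode))
      meta$population_mode else "marginal_independent"
  }
  disease_model(tab, prior, population_mode)
}

#' Write a disease-model specification table
#'
#' Writes the model's loci as TSV with `prior`, `population_mode` and
#' provenance recorded in leading `#` comment lines, at full numeric
#' precision. [read_model_spec()] restores the identical model.
#'
#' @param model A [disease_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "disease_model"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# polyrisk model spec v",
           utils::packageVersion("polyrisk")),
    paste0("# prior = ", .fmt(model$prior)),
    paste0("# population_mode = ", model$population_mode),
    "locus_id\tg0\trr\tweight"
  ), con)
  l <- model$loci
  writeLines(sprintf("%s\t%s\t%s\t%s", l$locus_id, .fmt(l$g0), .fmt(l$rr),
                     ifelse(is.na(l$weight), "NA", .fmt(l$weight))), con)
  invisible(path)
}

#' Read a genotype cohort
#'
#' Reads a delimited genotype matrix with columns `subject_id`, `label`,
#' then one column per locus holding categorical genotype states (`NA`
#' allowed). Leading `#` comments may carry provenance (`seed`, `design`,
#' ...), which is restored.
#'
#' @param path File path (TSV; CSV accepted).
#' @return A [cohort()].
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- .read_header_meta(path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "NA")
  if (!all(c("subject_id", "label") %in% names(tab))) {
    stop("cohort file must have subject_id and label columns")
  }
  loci <- setdiff(names(tab), c("subject_id", "label"))
  if (length(loci) == 0L) stop("cohort file has no locus columns")
  g <- as.matrix(tab[, loci, drop = FALSE])
  rownames(g) <- NULL
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  lev <- if (!is.null(meta$label_levels))
    strsplit(meta$label_levels, ",", fixed = TRUE)[[1]] else
    sort(unique(tab$label))
  cohort(g, factor(tab$label, levels = lev), subjects = tab$subject_id,
         provenance = meta)
}

#' Write a genotype cohort
#'
#' Writes the cohort as TSV (`subject_id`, `label`, one column per locus)
#' with provenance as leading `#` comment lines.
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  prov <- x$provenance
  prov$label_levels <- paste(levels(x$labels), collapse = ",")
  for (key in names(prov)) {
    v <- prov[[key]]
    if (length(v) == 1L && is.atomic(v)) {
      writeLines(paste0("# ", key, " = ", as.character(v)), con)
    }
  }
  writeLines(paste(c("subject_id", "label", colnames(x$genotypes)),
                   collapse = "\t"), con)
  body <- cbind(x$subjects, as.character(x$labels),
                apply(x$genotypes, 2L, as.character))
  body[is.na(body)] <- "NA"
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a sweep or metric table
#'
#' Writes any data frame as TSV at full numeric precision, with optional
#' provenance comment lines — the export format of the sweep functions and
#' of [ppd_distribution()] (`as.data.frame` of `support`/`mass`).
#'
#' @param records A data frame.
#' @param path Output file path.
#' @param provenance Optional named list written as `# key = value` lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, provenance = list()) {
  stopifnot(is.data.frame(records))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  provenance$package <- paste0("polyrisk ",
                               utils::packageVersion("polyrisk"))
  for (key in names(provenance)) {
    writeLines(paste0("# ", key, " = ", as.character(provenance[[key]])),
               con)
  }
  writeLines(paste(names(records), collapse = "\t"), con)
  cols <- lapply(records, function(v) {
    if (is.numeric(v)) .fmt(v) else as.character(v)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}
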