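#' Variable schema for a clinical cohort
#'
#' A schema lists, for every categorical predictor, its allowed categories,
#' its clinical role, the category contrasted against the rest when a crude
#' 2x2 odds ratio is needed (`severe_level`), and whether the variable is
#' excluded from the cluster hierarchy (e.g. witnessed apneas, which depend
#' on third-party reporting).
#'
#' @param name character vector of unique variable names.
#' @param categories list of character vectors (>= 2 categories each).
#' @param role one of `"demographic"`, `"exam"`, `"history"`,
#'   `"comorbidity"` per variable.
#' @param severe_level the exposed category used to binarize the variable
#'   for odds-ratio weighting.
#' @param exclusion_flag logical; `TRUE` marks variables screened but never
#'   entered into the cluster hierarchy.
#' @return A `variable_schema` data frame.
#' @export
variable_schema <- function(name, categories, role, severe_level,
                            exclusion_flag = FALSE) {
  stopifnot(length(name) == length(categories), !anyDuplicated(name))
  role <- match.arg(role, c("demographic", "exam", "history", "comorbidity"),
                    several.ok = TRUE)
  if (length(role) == 1L) role <- rep(role, length(name))
  if (length(exclusion_flag) == 1L) {
    exclusion_flag <- rep(exclusion_flag, length(name))
  }
  ncat <- vapply(categories, length, integer(1))
  if (any(ncat < 2L)) stop("every variable needs >= 2 categories")
  ok <- mapply(function(s, cats) s %in% cats, severe_level, categories)
  if (!all(ok)) stop("severe_level must be one of the variable's categories")
  out <- data.frame(name = name, role = role,
                    severe_level = unname(severe_level),
                    exclusion_flag = exclusion_flag,
                    stringsAsFactors = FALSE)
  out$categories <- unname(categories)
  class(out) <- c("variable_schema", "data.frame")
  out
}

schema_categories <- function(schema, variable) {
  schema$categories[[match(variable, schema$name)]]
}

#' Default predictor schema
#'
#' The 18 categorical predictors the screening analysis uses: the 14
#' cluster-hierarchy variables (demographics, exam, history, comorbidities)
#' plus the four symptom variables used only for screening comparators
#' (daytime sleepiness, snoring, witnessed apneas, gasping/choking).
#' Witnessed apneas carries the exclusion flag.
#'
#' @return A [variable_schema()] data frame with 18 rows.
#' @export
default_schema <- function() {
  yn <- c("no", "yes")
  variable_schema(
    name = c("gender", "age", "bmi",
             "nonrepairing_sleep", "nocturia",
             "stroke", "arterial_hypertension", "pulmonary_hypertension",
             "congestive_heart_failure", "arrhythmias", "pacemaker",
             "respiratory_changes", "diabetes", "dyslipidemia",
             "daytime_sleepiness", "snoring", "witnessed_apneas",
             "gasping_choking"),
    categories = list(
      c("female", "male"),
      c("20-44", "45-64", "65-90"),
      c("normal", "overweight", "obese"),
      yn, yn, yn, yn, yn, yn, yn, yn, yn, yn, yn, yn, yn, yn, yn),
    role = c("demographic", "demographic", "exam",
             rep("history", 2),
             rep("comorbidity", 9),
             rep("history", 4)),
    severe_level = c("male", "65-90", "obese",
                     rep("yes", 15)),
    exclusion_flag = c(rep(FALSE, 16), TRUE, FALSE)
  )
}

#' Construct a patient cohort
#'
#' Bundles the patient-level data frame with its variable schema and
#' (optionally) hidden ground truth carried by synthetic cohorts: the latent
#' phenotype each record was generated from and the pre-masking complete
#' values, used to score imputation.
#'
#' @param data data frame with columns `id`, one column per schema variable
#'   (character; `NA` = missing), `ahi` (non-negative integer), `severity`,
#'   `osa` (0/1).
#' @param schema a [variable_schema()].
#' @param truth optional list with elements `phenotype` (character vector)
#'   and/or `complete` (data frame of pre-masking predictor values).
#' @param imputed optional logical matrix flagging imputed cells.
#' @return An `osa_cohort` object.
#' @export
osa_cohort <- function(data, schema, truth = NULL, imputed = NULL) {
  needed <- c("id", schema$name, "ahi", "severity", "osa")
  miss <- setdiff(needed, names(data))
  if (length(miss)) {
    stop("cohort data lacks columns: ", paste(miss, collapse = ", "))
  }
  if (any(data$ahi < 0)) stop("ahi must be non-negative")
  bad_sev <- data$severity != classify_ahi(data$ahi)
  if (any(bad_sev)) stop("severity inconsistent with ahi for some records")
  if (any(data$osa != as.integer(data$ahi >= 5))) {
    stop("osa flag inconsistent with ahi >= 5")
  }
  for (v in schema$name) {
    vals <- data[[v]]
    ok <- is.na(vals) | vals %in% schema_categories(schema, v)
    if (!all(ok)) stop("invalid category in variable ", v)
  }
  structure(list(data = data, schema = schema, truth = truth,
                 imputed = imputed),
            class = "osa_cohort")
}

#' @export
print.osa_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("osa_cohort: %d patients (%d OSA, %d healthy), %d predictors\n",
              nrow(d), sum(d$osa == 1), sum(d$osa == 0),
              length(x$schema$name)))
  mp <- missing_proportions(x)
  cat(sprintf("  missing cells: %.1f%% overall\n", 100 * mean(mp)))
  if (!is.null(x$truth$phenotype)) cat("  latent phenotype stored\n")
  invisible(x)
}

#' @export
as.data.frame.osa_cohort <- function(x, ...) x$data

n_patients <- function(cohort) nrow(cohort$data)

#' Per-variable missingness proportions
#'
#' @param cohort an [osa_cohort()].
#' @return Named numeric vector, one proportion per schema variable.
#' @export
missing_proportions <- function(cohort) {
  vapply(cohort$schema$name,
         function(v) mean(is.na(cohort$data[[v]])),
         numeric(1))
}

#' Write / read the cohort CSV dialect
#'
#' One row per patient, one column per predictor (empty cell = missing),
#' plus `ahi`, `severity`, `osa` and, when present, `true_phenotype`.
#'
#' @param cohort an [osa_cohort()].
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `osa_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- cohort$data
  if (!is.null(cohort$truth$phenotype)) {
    d$true_phenotype <- cohort$truth$phenotype
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param schema schema to validate against (default [default_schema()]).
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", na.strings = "")
  d$ahi <- as.integer(d$ahi)
  d$osa <- as.integer(d$osa)
  truth <- NULL
  if ("true_phenotype" %in% names(d)) {
    truth <- list(phenotype = d$true_phenotype)
    d$true_phenotype <- NULL
  }
  osa_cohort(d, schema, truth = truth)
}
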