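#' Band an apnea-hypopnea index into severity levels
#'
#' Closed integer bands: 0-4 normal, 5-14 mild, 15-29 moderate, >= 30
#' severe. Vectorized.
#'
#' @param ahi non-negative events/hour.
#' @return Character vector of severity levels.
#' @export
classify_ahi <- function(ahi) {
  if (anyNA(ahi) || any(ahi < 0)) stop("ahi must be non-negative")
  cut(ahi, breaks = c(-Inf, 4, 14, 29, Inf),
      labels = severity_levels) |> as.character()
}

#' Discretize raw clinical measurements
#'
#' Applies the standard literature cutoffs: age 20-44 / 45-64 / 65-90; BMI
#' <25 normal, 25-30 overweight, >= 30 obese; neck circumference increased
#' above 37 cm (female) or 41 cm (male); abdominal circumference increased
#' above 80 cm (female) or 94 cm (male); Epworth Sleepiness Scale 0-10
#' normal, 11-24 excessive daytime sleepiness.
#'
#' @param raw named numeric vector; recognized names are `age`, `bmi`,
#'   `neck`, `abdominal`, `ess`.
#' @param gender `"female"` or `"male"`; required for circumference
#'   cutoffs — when missing, circumferences are returned as `NA`.
#' @return Named character vector of categories.
#' @export
discretize_measures <- function(raw, gender = NA_character_) {
  known <- c("age", "bmi", "neck", "abdominal", "ess")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown measurements: ", paste(bad, collapse = ", "))
  out <- character(0)
  if ("age" %in% names(raw)) {
    a <- raw[["age"]]
    if (is.na(a) || a < 18 || a > 110) stop("implausible age: ", a)
    out["age"] <- if (a < 45) "20-44" else if (a < 65) "45-64" else "65-90"
  }
  if ("bmi" %in% names(raw)) {
    b <- raw[["bmi"]]
    if (is.na(b) || b < 10 || b > 90) stop("implausible bmi: ", b)
    out["bmi"] <- if (b < 25) "normal" else if (b < 30) "overweight" else
      "obese"
  }
  circ <- function(value, female_cut, male_cut) {
    if (is.na(gender)) return(NA_character_)
    cutoff <- if (gender == "female") female_cut else male_cut
    if (value > cutoff) "increased" else "normal"
  }
  if ("neck" %in% names(raw)) {
    out["neck"] <- circ(raw[["neck"]], 37, 41)
  }
  if ("abdominal" %in% names(raw)) {
    out["abdominal"] <- circ(raw[["abdominal"]], 80, 94)
  }
  if ("ess" %in% names(raw)) {
    e <- raw[["ess"]]
    if (is.na(e) || e < 0 || e > 24) stop("ESS must lie in 0-24")
    out["ess"] <- if (e <= 10) "normal" else "excessive"
  }
  out
}

#' Remove variables with excessive missingness
#'
#' Variables whose missing proportion strictly exceeds `threshold` are
#' dropped from the cohort (and its schema); the removal list is reported.
#'
#' @param cohort an [osa_cohort()].
#' @param threshold proportion above which a variable is removed
#'   (default 0.80; a variable at exactly the threshold is retained).
#' @return List with elements `cohort` and `dropped`.
#' @export
drop_high_missing <- function(cohort, threshold = 0.80) {
  mp <- missing_proportions(cohort)
  dropped <- names(mp)[mp > threshold]
  if (length(dropped)) {
    keep <- setdiff(cohort$schema$name, dropped)
    schema <- cohort$schema[match(keep, cohort$schema$name), ]
    class(schema) <- class(cohort$schema)
    d <- cohort$data[, !(names(cohort$data) %in% dropped)]
    truth <- cohort$truth
    if (!is.null(truth$complete)) truth$complete <- truth$complete[keep]
    cohort <- osa_cohort(d, schema, truth = truth)
  }
  list(cohort = cohort, dropped = dropped)
}

#' Univariate association screening
#'
#' Tests each predictor against the outcome on its non-missing rows:
#' chi-square unless any expected cell count falls below 5, in which case
#' the Fisher exact test is used. The default contrast is the three-level
#' severity comparison among OSA patients; the binary OSA-vs-healthy
#' contrast is available.
#'
#' @param cohort an [osa_cohort()].
#' @param alpha significance level (default 0.20).
#' @param contrast `"severity"` (mild/moderate/severe among OSA, default)
#'   or `"osa"` (binary).
#' @return A `screening_result` data frame with columns `variable`, `test`,
#'   `p_value`, `significant`.
#' @export
univariate_screen <- function(cohort, alpha = 0.20,
                              contrast = c("severity", "osa")) {
  contrast <- match.arg(contrast)
  d <- cohort$data
  if (contrast == "severity") {
    d <- d[d$osa == 1L, ]
    outcome <- factor(d$severity, levels = c("mild", "moderate", "severe"))
  } else {
    outcome <- factor(d$osa, levels = c(0L, 1L))
  }
  rows <- lapply(cohort$schema$name, function(v) {
    vals <- d[[v]]
    keep <- !is.na(vals)
    tab <- table(vals[keep], outcome[keep])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      return(data.frame(variable = v, test = "untestable", p_value = NA_real_,
                        significant = FALSE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab, workspace = 2e6)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi-square"
    }
    data.frame(variable = v, test = test, p_value = p,
               significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "contrast") <- contrast
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Final cluster-variable selection
#'
#' A variable enters the cluster hierarchy when it screens significant on
#' BOTH the original and the imputed cohort and is not exclusion-flagged.
#'
#' @param screen_original,screen_imputed [univariate_screen()] results.
#' @param schema the cohort's [variable_schema()].
#' @return Character vector of selected variable names.
#' @export
select_cluster_variables <- function(screen_original, screen_imputed,
                                     schema) {
  sig <- intersect(
    screen_original$variable[screen_original$significant],
    screen_imputed$variable[screen_imputed$significant])
  setdiff(sig, schema$name[schema$exclusion_flag])
}

# Simple-matching distance from one record to every row of a character
# matrix, over the given variables; pairs with no shared observed variable
# get distance 1 (maximally dissimilar).
.matching_distance <- function(target, mat, vars) {
  mm <- matrix(0L, nrow(mat), length(vars))
  obs <- matrix(FALSE, nrow(mat), length(vars))
  for (j in seq_along(vars)) {
    tv <- target[[vars[j]]]
    cv <- mat[, vars[j]]
    ok <- !is.na(tv) & !is.na(cv)
    obs[, j] <- ok
    mm[ok, j] <- as.integer(cv[ok] != tv)
  }
  shared <- rowSums(obs)
  d <- rowSums(mm) / pmax(shared, 1L)
  d[shared == 0L] <- 1
  d
}

# Modal category among k nearest donors; ties broken by the category more
# frequent in the full cohort, then lexicographically.
.vote <- function(donor_values, cohort_freq) {
  tab <- table(donor_values)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    f <- cohort_freq[top]
    f[is.na(f)] <- 0
    top <- top[f == max(f)]
    top <- sort(top)[1L]
  }
  top
}

#' Stepwise k-nearest-neighbour imputation
#'
#' Implements the four-step schedule: high-missing variables are assumed
#' already removed; remaining incomplete variables are ranked ascending by
#' missing proportion; a first pass imputes incomplete *significant*
#' variables using distances computed on complete + significant variables
#' only; the remaining incomplete variables are then imputed one at a time
#' in rank order, each using all currently complete or imputed variables.
#' Each missing cell receives the modal category among its `k` nearest
#' neighbours under the simple-matching distance (donors tied with the
#' k-th nearest are all included, the canonical k-NN resolution under a
#' discrete distance); vote ties go to the category more frequent in the
#' full cohort, then lexicographic order. The (always complete) outcome
#' severity band joins the matching basis by default, following the
#' standard advice to include the outcome when imputing predictors.
#'
#' @param cohort an [osa_cohort()] with high-missing variables dropped.
#' @param screening a [univariate_screen()] result on this cohort.
#' @param k number of neighbour donors (default 10).
#' @param include_outcome add the severity band to the matching basis
#'   (default `TRUE`).
#' @return The imputed cohort; imputed cells are flagged in `$imputed`.
#' @export
impute_stepwise_knn <- function(cohort, screening, k = 10,
                                include_outcome = TRUE) {
  d <- cohort$data
  vars <- cohort$schema$name
  if (include_outcome) {
    d$.severity_band <- d$severity
  }
  mp <- missing_proportions(cohort)
  sig <- screening$variable[screening$significant]
  complete_vars <- names(mp)[mp == 0]
  if (include_outcome) {
    complete_vars <- c(complete_vars, ".severity_band")
  }
  incomplete <- names(sort(mp[mp > 0]))
  flags <- matrix(FALSE, nrow(d), length(vars),
                  dimnames = list(NULL, vars))
  if (!length(incomplete)) {
    return(osa_cohort(cohort$data, cohort$schema, truth = cohort$truth,
                      imputed = flags))
  }

  impute_one <- function(v, predictor_vars) {
    predictor_vars <- setdiff(predictor_vars, v)
    targets <- which(is.na(d[[v]]))
    donors_all <- !is.na(d[[v]])
    freq <- table(d[[v]][donors_all]) / sum(donors_all)
    mat <- as.matrix(d[predictor_vars])
    for (i in targets) {
      dist <- .matching_distance(d[i, predictor_vars, drop = FALSE],
                                 mat, predictor_vars)
      cand <- which(donors_all)
      if (length(cand) < k) {
        warning("fewer than ", k, " donors for ", v, "; using all ",
                length(cand), call. = FALSE)
      }
      dd <- dist[cand]
      # all donors tied with the k-th nearest are included: under a
      # discrete matching distance the k-NN set is otherwise ill-defined
      thr <- sort(dd)[min(k, length(dd))]
      nn <- cand[dd <= thr + 1e-12]
      d[[v]][i] <<- .vote(d[[v]][nn], freq)
      flags[i, v] <<- TRUE
    }
  }

  # Pass 1: incomplete significant variables, distances on
  # complete + significant variables only.
  pass1 <- incomplete[incomplete %in% sig]
  basis1 <- union(complete_vars, sig)
  for (v in pass1) impute_one(v, basis1)
  # Pass 2: the rest, one at a time in rank order, each using everything
  # imputed or complete so far.
  done <- union(complete_vars, pass1)
  for (v in setdiff(incomplete, pass1)) {
    impute_one(v, done)
    done <- union(done, v)
  }
  d$.severity_band <- NULL
  osa_cohort(d, cohort$schema, truth = cohort$truth, imputed = flags)
}
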