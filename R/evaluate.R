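#' Clopper-Pearson exact binomial 95% interval
#'
#' @param x success count.
#' @param n trials (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
proportion_ci <- function(x, n, conf_level = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(x >= 0, x <= n)
  as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores with the strict "score >
#' threshold" positivity rule; the AUC is the trapezoid-rule area, which
#' equals the normalized Mann-Whitney U statistic with ties counted half.
#'
#' @param scores numeric classifier scores (e.g. posterior probabilities).
#' @param labels 0/1 outcome per score.
#' @return An `osa_roc` object: data frame of `(threshold, sens, spec)`
#'   plus `auc`, and the raw scores/labels for cutoff selection.
#' @export
roc_and_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("need at least one positive and one negative")
  }
  ths <- c(-Inf, sort(unique(scores)))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(ths, function(t) mean(pos > t), numeric(1))
  spec <- vapply(ths, function(t) mean(neg <= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(points = data.frame(threshold = ths, sens = sens,
                                     spec = spec),
                 auc = auc, scores = scores, labels = labels),
            class = "osa_roc")
}

#' @export
print.osa_roc <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Rule-out cutoff at a target sensitivity
#'
#' Scans integer-percent thresholds (positivity rule: posterior > t/100)
#' and returns the largest threshold whose derivation-sample sensitivity
#' still meets the target — the highest-specificity cutoff compatible with
#' the rule-out requirement. When no threshold achieves the target the
#' lowest (0) is returned with a warning.
#'
#' @param roc an [roc_and_auc()] object from the derivation sample.
#' @param target_sensitivity required sensitivity (default 0.95).
#' @return Integer cutoff in percent.
#' @export
choose_cutoff <- function(roc, target_sensitivity = 0.95) {
  pos <- roc$scores[roc$labels == 1L]
  sens <- vapply(0:100, function(t) mean(pos > t / 100), numeric(1))
  ok <- which(sens >= target_sensitivity)
  if (!length(ok)) {
    warning("no cutoff achieves the target sensitivity; returning 0")
    return(0L)
  }
  as.integer(max(ok - 1L))
}

# Simel log-method CI for a likelihood ratio.
.lr_ci <- function(lr, num_x, num_n, den_x, den_n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (min(num_x, den_x) == 0 || !is.finite(lr) || lr <= 0) {
    return(c(NA_real_, NA_real_))
  }
  se <- sqrt((1 - num_x / num_n) / num_x + (1 - den_x / den_n) / den_x)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic-test metric panel from confusion counts
#'
#' Sensitivity, specificity, accuracy, predictive values (Clopper-Pearson
#' 95% CIs), likelihood ratios (log-method CIs), and the diagnostic odds
#' ratio `DOR = LR+ / LR- = (tp * tn) / (fp * fn)` (Haldane +0.5 in every
#' count when any count is zero).
#'
#' @param tp,fp,tn,fn confusion counts; `tp + fn > 0` and `tn + fp > 0`.
#' @param cutoff,auc optional annotations carried into the result.
#' @return A `diagnostic_metrics` list.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn, cutoff = NA, auc = NA) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) stop("empty outcome margin")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  if (min(tp, fp, tn, fn) == 0) {
    h <- 0.5
    dor <- ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))
  } else {
    dor <- lr_pos / lr_neg
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, accuracy = acc,
    ppv = ppv, npv = npv,
    lr_pos = lr_pos, lr_neg = lr_neg, dor = dor,
    cutoff = cutoff, auc = auc,
    ci = list(
      sensitivity = proportion_ci(tp, tp + fn),
      specificity = proportion_ci(tn, tn + fp),
      accuracy = proportion_ci(tp + tn, tp + fp + tn + fn),
      ppv = if (tp + fp > 0) proportion_ci(tp, tp + fp) else c(NA, NA),
      npv = if (tn + fn > 0) proportion_ci(tn, tn + fn) else c(NA, NA),
      lr_pos = .lr_ci(lr_pos, tp, tp + fn, fp, fp + tn),
      lr_neg = .lr_ci(lr_neg, fn, tp + fn, tn, fp + tn))),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf(
    "sens %.2f  spec %.2f  acc %.2f  ppv %.2f  npv %.2f\n",
    x$sensitivity, x$specificity, x$accuracy, x$ppv, x$npv))
  cat(sprintf("LR+ %.2f  LR- %.2f  DOR %.2f\n", x$lr_pos, x$lr_neg, x$dor))
  invisible(x)
}

#' Posttest probability via Bayes' odds chain (Fagan nomogram)
#'
#' `pretest odds = p / (1 - p)`; `posttest odds = pretest odds * LR`;
#' `posttest probability = odds / (1 + odds)`.
#'
#' @param pretest_probability pretest probability in (0, 1).
#' @param lr positive likelihood ratio of the observed result.
#' @return List with the pretest/posttest odds and probabilities.
#' @export
posttest <- function(pretest_probability, lr) {
  if (pretest_probability <= 0 || pretest_probability >= 1) {
    stop("pretest probability must lie strictly inside (0, 1)")
  }
  if (lr <= 0) stop("likelihood ratio must be positive")
  pre_odds <- pretest_probability / (1 - pretest_probability)
  post_odds <- pre_odds * lr
  list(pretest_probability = pretest_probability,
       pretest_odds = pre_odds,
       posttest_odds = post_odds,
       posttest_probability = post_odds / (1 + post_odds))
}

#' Symptom-based moderate-to-severe risk rule (guideline comparator)
#'
#' Flags a patient when excessive daytime sleepiness is present together
#' with at least two of: habitual loud snoring, witnessed apnea or
#' gasping/choking, diagnosed arterial hypertension. Missing ingredients
#' are treated as absent; rows where that happened are flagged in the
#' `"missing_ingredient"` attribute.
#'
#' @param data data frame with columns `daytime_sleepiness`, `snoring`,
#'   `witnessed_apneas`, `gasping_choking`, `arterial_hypertension`.
#' @return Logical vector of risk flags.
#' @export
aasm_rule <- function(data) {
  yes <- function(v) !is.na(data[[v]]) & data[[v]] == "yes"
  ingredients <- c("daytime_sleepiness", "snoring", "witnessed_apneas",
                   "gasping_choking", "arterial_hypertension")
  miss <- setdiff(ingredients, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  criteria <- yes("snoring") +
    (yes("witnessed_apneas") | yes("gasping_choking")) +
    yes("arterial_hypertension")
  flag <- yes("daytime_sleepiness") & criteria >= 2
  any_missing <- Reduce(`|`, lapply(ingredients,
                                    function(v) is.na(data[[v]])))
  attr(flag, "missing_ingredient") <- any_missing
  flag
}

.metrics_at_cutoff <- function(scores, labels, cutoff, auc = NA) {
  pred <- scores > cutoff / 100
  diagnostic_metrics(tp = sum(pred & labels == 1L),
                     fp = sum(pred & labels == 0L),
                     tn = sum(!pred & labels == 0L),
                     fn = sum(!pred & labels == 1L),
                     cutoff = cutoff, auc = auc)
}

# Fit the requested model on `train` and score `test`. For model B the
# phenotyping chain (weights, dendrogram, aggregation, assignment) is refit
# on the training fold only, unless fixed assignments are supplied
# (ph_train/ph_test), in which case the fold reuses them.
.fit_and_score <- function(train, test, model_kind, predictors,
                           cluster_vars, alpha, k_fine, method,
                           ph_train = NULL, ph_test = NULL) {
  if (model_kind == "A") {
    m <- fit_model_a(train, predictors, alpha = alpha)
    return(predict(m, test$data))
  }
  if (is.null(ph_train)) {
    n_train_osa <- sum(train$data$osa == 1L)
    pm <- fit_phenotypes(train, cluster_vars,
                         k_fine = min(k_fine, n_train_osa),
                         method = method)
    ph_train <- assign_phenotype(train$data, pm)$phenotype
    ph_test <- assign_phenotype(test$data, pm)$phenotype
  }
  m <- fit_model_b(train, predictors, ph_train, alpha = alpha)
  predict(m, test$data, phenotype = ph_test)
}

.subset_cohort <- function(cohort, idx) {
  osa_cohort(cohort$data[idx, , drop = FALSE], cohort$schema)
}

#' Cross-validated screening performance
#'
#' Fits and evaluates model A (naive Bayes) or model B
#' (phenotype-augmented) under leave-one-out or 10-times-twofold
#' stratified cross-validation. By default, inside every training fold of
#' model B the whole phenotyping chain is refit and held-out patients are
#' assigned by affinity, so no cluster information leaks. With
#' `refit_phenotypes = FALSE` the phenotypes are instead fit once on the
#' full cohort and their assignments reused in every fold — the protocol
#' of studies that define phenotypes before validation; note that this
#' lets cluster information from held-out patients into training. The
#' screening cutoff is chosen once on the derivation (full-sample) ROC at
#' the target sensitivity and applied to every fold.
#'
#' @param cohort an imputed [osa_cohort()].
#' @param model_kind `"A"` or `"B"`.
#' @param scheme `"10x2cv"` (default) or `"loo"`.
#' @param seed integer seed for the repeated splits.
#' @param predictors classifier predictors (default: the cluster variables).
#' @param cluster_vars variables for the phenotype refits (model B).
#' @param target_sensitivity rule-out target (default 0.95).
#' @param cutoff override the derivation-chosen cutoff (integer percent).
#' @param alpha Laplace pseudo-count.
#' @param k_fine,method phenotyping settings (model B).
#' @param refit_phenotypes refit phenotyping inside each training fold
#'   (default `TRUE`, leakage-free).
#' @param reps repetitions of the twofold split (default 10).
#' @return A `validation_report`: derivation ROC/AUC/cutoff, pooled CV
#'   metrics with CIs, per-fold estimates, per-repetition AUCs.
#' @export
cross_validate <- function(cohort, model_kind = c("A", "B"),
                           scheme = c("10x2cv", "loo"), seed = 1L,
                           predictors = cluster_vars,
                           cluster_vars,
                           target_sensitivity = 0.95, cutoff = NULL,
                           alpha = 1, k_fine = 10, method = "ward.D",
                           refit_phenotypes = TRUE, reps = 10) {
  model_kind <- match.arg(model_kind)
  scheme <- match.arg(scheme)
  d <- cohort$data
  n <- nrow(d)

  ph_all <- NULL
  if (model_kind == "B" && !refit_phenotypes) {
    pm_all <- fit_phenotypes(cohort, cluster_vars, k_fine = k_fine,
                             method = method)
    ph_all <- assign_phenotype(d, pm_all)$phenotype
  }
  fold_phen <- function(train_idx, test_idx) {
    if (is.null(ph_all)) list(train = NULL, test = NULL) else
      list(train = ph_all[train_idx], test = ph_all[test_idx])
  }

  # Derivation fit: scores on the full sample, cutoff at target sensitivity.
  deriv_scores <- .fit_and_score(cohort, cohort, model_kind, predictors,
                                 cluster_vars, alpha, k_fine, method,
                                 ph_train = ph_all, ph_test = ph_all)
  deriv_roc <- roc_and_auc(deriv_scores, d$osa)
  if (is.null(cutoff)) {
    cutoff <- choose_cutoff(deriv_roc, target_sensitivity)
  }

  if (scheme == "loo") {
    cv_scores <- vapply(seq_len(n), function(i) {
      phs <- fold_phen(setdiff(seq_len(n), i), i)
      .fit_and_score(.subset_cohort(cohort, -i), .subset_cohort(cohort, i),
                     model_kind, predictors, cluster_vars, alpha, k_fine,
                     method, ph_train = phs$train, ph_test = phs$test)
    }, numeric(1))
    roc <- roc_and_auc(cv_scores, d$osa)
    metrics <- .metrics_at_cutoff(cv_scores, d$osa, cutoff, auc = roc$auc)
    report <- list(scheme = scheme, model = model_kind, cutoff = cutoff,
                   derivation = deriv_roc, roc = roc, auc = roc$auc,
                   metrics = metrics, scores = cv_scores, seed = seed)
  } else {
    fold_metrics <- list()
    rep_auc <- numeric(0)
    with_seed(seed, {
      for (rep in seq_len(reps)) {
        # Stratified half/half split: permute within outcome class.
        fold <- integer(n)
        for (s in 0:1) {
          idx <- sample(which(d$osa == s))
          fold[idx] <- rep_len(1:2, length(idx))
        }
        rep_scores <- numeric(n)
        for (f in 1:2) {
          test_idx <- which(fold == f)
          train <- .subset_cohort(cohort, -test_idx)
          test <- .subset_cohort(cohort, test_idx)
          if (length(unique(train$data$osa)) < 2L) {
            warning("single-class training fold skipped")
            rep_scores[test_idx] <- NA_real_
            next
          }
          phs <- fold_phen(which(fold != f), test_idx)
          sc <- .fit_and_score(train, test, model_kind, predictors,
                               cluster_vars, alpha, k_fine, method,
                               ph_train = phs$train, ph_test = phs$test)
          rep_scores[test_idx] <- sc
          fold_metrics[[length(fold_metrics) + 1L]] <-
            .metrics_at_cutoff(sc, test$data$osa, cutoff)
        }
        ok <- !is.na(rep_scores)
        rep_auc <- c(rep_auc, roc_and_auc(rep_scores[ok], d$osa[ok])$auc)
      }
    })
    pick <- function(field) {
      vapply(fold_metrics, function(m) m[[field]], numeric(1))
    }
    ci_normal <- function(x) {
      mean(x) + c(-1, 1) * stats::qnorm(0.975) * stats::sd(x) /
        sqrt(length(x))
    }
    fields <- c("sensitivity", "specificity", "accuracy", "ppv", "npv",
                "lr_pos", "lr_neg", "dor")
    summary <- lapply(fields, function(f) {
      x <- pick(f)
      x <- x[is.finite(x)]
      list(mean = mean(x), ci = ci_normal(x))
    })
    names(summary) <- fields
    report <- list(scheme = scheme, model = model_kind, cutoff = cutoff,
                   derivation = deriv_roc,
                   auc = mean(rep_auc), auc_ci = ci_normal(rep_auc),
                   rep_auc = rep_auc,
                   metrics = summary, fold_metrics = fold_metrics,
                   seed = seed)
  }
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: model %s, %s, cutoff %d%%\n",
              x$model, x$scheme, x$cutoff))
  cat(sprintf("  derivation AUC %.3f; validated AUC %.3f\n",
              x$derivation$auc, x$auc))
  if (x$scheme == "10x2cv") {
    m <- x$metrics
    cat(sprintf("  sens %.2f  spec %.2f  DOR %.2f (fold means)\n",
                m$sensitivity$mean, m$specificity$mean, m$dor$mean))
  } else {
    print(x$metrics)
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a [cross_validate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  x <- report
  x$derivation <- list(auc = report$derivation$auc,
                       points = report$derivation$points)
  if (!is.null(x$roc)) x$roc <- list(auc = x$roc$auc, points = x$roc$points)
  x$fold_metrics <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
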