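# Discrete Bayesian classifiers for OSA screening.
#
# Model A: naive Bayes — each predictor's only parent is the binary OSA
# outcome. Model B: a 3-state phenotype node is added as a parent of every
# predictor (predictor parents = {OSA, phenotype}); by default the
# phenotype is a root node (it influences OSA only through the predictors'
# conditional tables), with an optional OSA -> phenotype arc variant.
# Conditional tables are Laplace-smoothed with pseudo-count alpha; the OSA
# prior is the empirical outcome frequency.

.smoothed_table <- function(values, categories, alpha) {
  counts <- table(factor(values, levels = categories))
  p <- (as.numeric(counts) + alpha) / (sum(counts) + alpha * length(categories))
  stats::setNames(p, categories)
}

#' Fit the naive Bayes screening classifier (model A)
#'
#' `P(OSA)` is the empirical outcome frequency; each predictor's
#' conditional table is `P(x_j = v | OSA = s) = (count + alpha) /
#' (total + alpha * n_categories)`.
#'
#' @param cohort an imputed [osa_cohort()] with OSA and healthy patients.
#' @param predictors predictor variable names.
#' @param alpha Laplace pseudo-count (default 1).
#' @return An `osa_bayes` model, structure `"A"`.
#' @export
fit_model_a <- function(cohort, predictors, alpha = 1) {
  d <- cohort$data
  miss <- setdiff(predictors, names(d))
  if (length(miss)) stop("predictors absent: ", paste(miss, collapse = ", "))
  cats <- lapply(predictors, function(v) schema_categories(cohort$schema, v))
  names(cats) <- predictors
  cpts <- lapply(predictors, function(v) {
    vapply(c(`0` = 0L, `1` = 1L), function(s) {
      .smoothed_table(d[[v]][d$osa == s], cats[[v]], alpha)
    }, numeric(length(cats[[v]])))
  })
  names(cpts) <- predictors
  structure(list(structure = "A",
                 prior = mean(d$osa == 1L),
                 categories = cats,
                 cpts = cpts,
                 alpha = alpha),
            class = "osa_bayes")
}

#' Fit the phenotype-augmented classifier (model B)
#'
#' Adds the 3-state phenotype node as a parent of every predictor, so each
#' conditional table has 6 parent configurations (OSA x phenotype), each
#' Laplace-smoothed. A parent configuration with zero training rows gets
#' the uniform column implied by smoothing, with a warning.
#'
#' @param cohort an imputed [osa_cohort()].
#' @param predictors predictor variable names.
#' @param phenotype assigned phenotype per cohort row (from
#'   [assign_phenotype()]).
#' @param alpha Laplace pseudo-count (default 1).
#' @param osa_parent when `TRUE`, model the phenotype with an OSA ->
#'   phenotype arc (`P(phenotype | OSA)`); default is a root phenotype node
#'   with its marginal distribution.
#' @return An `osa_bayes` model, structure `"B"`.
#' @export
fit_model_b <- function(cohort, predictors, phenotype, alpha = 1,
                        osa_parent = FALSE) {
  d <- cohort$data
  stopifnot(length(phenotype) == nrow(d),
            all(phenotype %in% phenotype_levels))
  miss <- setdiff(predictors, names(d))
  if (length(miss)) stop("predictors absent: ", paste(miss, collapse = ", "))
  cats <- lapply(predictors, function(v) schema_categories(cohort$schema, v))
  names(cats) <- predictors
  empty_configs <- 0L
  cpts <- lapply(predictors, function(v) {
    arr <- array(NA_real_,
                 dim = c(length(cats[[v]]), 2L, 3L),
                 dimnames = list(cats[[v]], c("0", "1"), phenotype_levels))
    for (s in 0:1) {
      for (ph in phenotype_levels) {
        rows <- d$osa == s & phenotype == ph
        if (!any(rows)) empty_configs <<- empty_configs + 1L
        arr[, as.character(s), ph] <-
          .smoothed_table(d[[v]][rows], cats[[v]], alpha)
      }
    }
    arr
  })
  if (empty_configs > 0L) {
    warning(empty_configs,
            " parent configuration(s) had no training rows; their columns ",
            "are uniform (smoothing only)")
  }
  names(cpts) <- predictors
  phen_prior <- if (osa_parent) {
    vapply(c(`0` = 0L, `1` = 1L), function(s) {
      .smoothed_table(phenotype[d$osa == s], phenotype_levels, alpha)
    }, numeric(3))
  } else {
    .smoothed_table(phenotype, phenotype_levels, alpha)
  }
  structure(list(structure = "B",
                 prior = mean(d$osa == 1L),
                 categories = cats,
                 cpts = cpts,
                 phenotype_prior = phen_prior,
                 osa_parent = osa_parent,
                 alpha = alpha),
            class = "osa_bayes")
}

#' @export
print.osa_bayes <- function(x, ...) {
  cat(sprintf("osa_bayes model %s: %d predictors, alpha = %g, P(OSA) = %.3f\n",
              x$structure, length(x$cpts), x$alpha, x$prior))
  invisible(x)
}

#' Posterior probability of OSA given partial evidence
#'
#' Exact inference by enumeration over the outcome (and the phenotype when
#' unobserved). Absent predictors marginalize out exactly because every
#' predictor is a leaf, so only observed evidence enters the product.
#'
#' @param model an `osa_bayes` model.
#' @param evidence named list/vector of observed predictor categories
#'   (possibly empty).
#' @param phenotype optional phenotype evidence (model B only).
#' @return `P(OSA = 1 | evidence)`.
#' @export
posterior_osa <- function(model, evidence = NULL, phenotype = NULL) {
  evidence <- as.list(evidence)
  for (v in names(evidence)) {
    if (!v %in% names(model$cpts)) stop("unknown predictor: ", v)
    if (!evidence[[v]] %in% model$categories[[v]]) {
      stop("invalid category '", evidence[[v]], "' for ", v)
    }
  }
  if (model$structure == "A") {
    lik <- vapply(c("0", "1"), function(s) {
      p <- if (s == "1") model$prior else 1 - model$prior
      for (v in names(evidence)) {
        p <- p * model$cpts[[v]][evidence[[v]], s]
      }
      p
    }, numeric(1))
  } else {
    phs <- if (is.null(phenotype)) phenotype_levels else phenotype
    if (!all(phs %in% phenotype_levels)) {
      stop("invalid phenotype evidence: ", phenotype)
    }
    lik <- vapply(c("0", "1"), function(s) {
      total <- 0
      for (ph in phs) {
        p_ph <- if (isTRUE(model$osa_parent)) {
          model$phenotype_prior[ph, s]
        } else {
          model$phenotype_prior[[ph]]
        }
        p <- (if (s == "1") model$prior else 1 - model$prior) * p_ph
        for (v in names(evidence)) {
          p <- p * model$cpts[[v]][evidence[[v]], s, ph]
        }
        total <- total + p
      }
      total
    }, numeric(1))
  }
  unname(lik["1"] / sum(lik))
}

#' Posterior for every row of a cohort
#'
#' @param object an `osa_bayes` model.
#' @param newdata data frame holding the model's predictors.
#' @param phenotype optional phenotype per row (model B evidence);
#'   marginalized out when `NULL` or `NA` for a row.
#' @param ... unused.
#' @return Numeric vector of `P(OSA = 1 | evidence)` per row.
#' @export
predict.osa_bayes <- function(object, newdata, phenotype = NULL, ...) {
  vars <- names(object$cpts)
  vapply(seq_len(nrow(newdata)), function(i) {
    ev <- as.list(newdata[i, vars, drop = FALSE])
    ev <- ev[!vapply(ev, is.na, logical(1))]
    ph <- if (is.null(phenotype) || is.na(phenotype[i])) NULL else
      phenotype[i]
    posterior_osa(object, ev, phenotype = ph)
  }, numeric(1))
}

#' Serialize a fitted classifier to JSON
#'
#' @param model an `osa_bayes` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bayes_model <- function(model, path) {
  x <- unclass(model)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}
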