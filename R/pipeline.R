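#' Pipeline configuration
#'
#' Collects every tunable of the study replica in one validated object. The
#' input is either a generator spec (synthetic cohort) or a cohort CSV
#' path; all randomness is controlled by explicit seeds.
#'
#' @param spec a [generator_spec()], or `NULL` when `input_csv` is given.
#' @param input_csv path to a cohort CSV (alternative to `spec`).
#' @param alpha_screen univariate screening level (default 0.20).
#' @param drop_threshold missingness removal threshold (default 0.80).
#' @param k_impute imputation neighbours (default 10).
#' @param k_fine fine cluster cut (default 10).
#' @param ward Ward variant (default `"ward.D"`).
#' @param normalize normalize the patient distance by total weight.
#' @param alpha_bayes Laplace pseudo-count (default 1).
#' @param target_sensitivity rule-out target (default 0.95).
#' @param cv_scheme `"10x2cv"` or `"loo"`.
#' @param seed master seed.
#' @param out_dir output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spec = NULL, input_csv = NULL,
                            alpha_screen = 0.20, drop_threshold = 0.80,
                            k_impute = 10, k_fine = 10,
                            ward = "ward.D", normalize = FALSE,
                            alpha_bayes = 1, target_sensitivity = 0.95,
                            cv_scheme = "10x2cv", seed = 1L,
                            out_dir = NULL) {
  if (is.null(spec) && is.null(input_csv)) {
    stop("supply a generator spec or an input CSV path")
  }
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    stop("input CSV not found: ", input_csv)
  }
  structure(list(spec = spec, input_csv = input_csv,
                 alpha_screen = alpha_screen,
                 drop_threshold = drop_threshold,
                 k_impute = k_impute, k_fine = k_fine, ward = ward,
                 normalize = normalize, alpha_bayes = alpha_bayes,
                 target_sensitivity = target_sensitivity,
                 cv_scheme = cv_scheme, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full screening-study replica
#'
#' Fixed stage order: generate (or load) the cohort, drop high-missing
#' variables, screen the original cohort, impute, screen the imputed
#' cohort, select the cluster variables (significant in both screenings,
#' minus exclusion-flagged), compute odds-ratio weights, cluster OSA
#' patients into phenotypes, assign every patient by affinity, fit models
#' A and B, and cross-validate both. When `config$out_dir` is set, every
#' stage artifact plus a run manifest is written there.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list with all stage objects (`cohort`, `screening`,
#'   `imputed`, `selected`, `phenotypes`, `assignment`, `model_a`,
#'   `model_b`, `report_a`, `report_b`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "generate"
  out <- list()
  res <- tryCatch({
    if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- spec$seed %||% config$seed
      cohort <- generate_cohort(spec)
      cohort <- inject_missingness(cohort, spec)
    } else {
      cohort <- read_cohort_csv(config$input_csv)
    }
    out$cohort <- cohort

    stage <- "drop_high_missing"
    dropped <- drop_high_missing(cohort, config$drop_threshold)
    cohort <- dropped$cohort
    out$dropped <- dropped$dropped

    stage <- "screen_original"
    screen_orig <- univariate_screen(cohort, alpha = config$alpha_screen)
    out$screening <- screen_orig

    stage <- "impute"
    imputed <- impute_stepwise_knn(cohort, screen_orig,
                                   k = config$k_impute)
    out$imputed <- imputed

    stage <- "screen_imputed"
    screen_imp <- univariate_screen(imputed, alpha = config$alpha_screen)
    out$screening_imputed <- screen_imp

    stage <- "select_variables"
    selected <- select_cluster_variables(screen_orig, screen_imp,
                                         cohort$schema)
    if (length(selected) < 2L) stop("fewer than 2 cluster variables selected")
    out$selected <- selected

    stage <- "phenotype"
    pm <- fit_phenotypes(imputed, selected, k_fine = config$k_fine,
                         method = config$ward,
                         normalize = config$normalize)
    out$phenotypes <- pm

    stage <- "assign"
    assignment <- assign_phenotype(imputed$data, pm)
    out$assignment <- assignment

    stage <- "fit"
    out$model_a <- fit_model_a(imputed, selected,
                               alpha = config$alpha_bayes)
    out$model_b <- fit_model_b(imputed, selected, assignment$phenotype,
                               alpha = config$alpha_bayes)

    stage <- "evaluate"
    out$report_a <- cross_validate(
      imputed, "A", scheme = config$cv_scheme, seed = config$seed,
      cluster_vars = selected, alpha = config$alpha_bayes,
      target_sensitivity = config$target_sensitivity,
      k_fine = config$k_fine, method = config$ward)
    out$report_b <- cross_validate(
      imputed, "B", scheme = config$cv_scheme, seed = config$seed,
      cluster_vars = selected, alpha = config$alpha_bayes,
      target_sensitivity = config$target_sensitivity,
      k_fine = config$k_fine, method = config$ward)
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg <- config
  cfg$spec <- NULL
  cfg$out_dir <- NULL   # manifests identify the analysis, not its location
  res$manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    config_hash = fnv1a32(c(cfg, list(spec = unclass(config$spec)))),
    seed = config$seed,
    selected_variables = res$selected,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("phenoscreen")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_cohort_csv(res$cohort, p("cohort.csv"))
    jsonlite::write_json(res$screening, p("screening.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_cohort_csv(res$imputed, p("imputed.csv"))
    write_phenotype_model(res$phenotypes, p("phenotype_model.json"))
    write_bayes_model(res$model_a, p("model_a.json"))
    write_bayes_model(res$model_b, p("model_b.json"))
    write_validation_report(res$report_a, p("validation_a.json"))
    write_validation_report(res$report_b, p("validation_b.json"))
    jsonlite::write_json(res$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(res)
}
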