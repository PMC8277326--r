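#' Synthetic cohort generator specification
#'
#' A generator spec fixes the cohort sizes, the latent phenotype mixture for
#' OSA and healthy patients, the per-variable category distributions
#' conditional on (phenotype, OSA status), the severity mixture within each
#' phenotype, the integer AHI band per severity level, and the per-variable
#' missingness rates and mechanism. Records are drawn conditionally
#' independently given (phenotype, status).
#'
#' @param n_osa,n_healthy cohort sizes (positive integers).
#' @param phenotype_weights_osa,phenotype_weights_healthy length-3 simplexes
#'   over phenotypes (low, medium, high).
#' @param variables named list; each element has matrices `osa` and
#'   `healthy` (3 phenotype rows x categories, rows sum to 1) giving
#'   category probabilities.
#' @param severity_mix 3x3 matrix, rows = phenotypes, columns =
#'   mild/moderate/severe, rows sum to 1 (OSA patients only).
#' @param ahi_bands named list of integer `c(lo, hi)` per severity level;
#'   bands must be disjoint and ordered.
#' @param missing_rate named numeric vector of per-variable missingness
#'   proportions in `[0, 1]`.
#' @param missing_mechanism `"MCAR"` or `"MAR"`; under MAR a variable's rate
#'   is multiplied by `mar_healthy_factor` for healthy patients (capped at
#'   1), emulating under-recording of comorbidities in healthier charts.
#' @param mar_healthy_factor multiplier applied under MAR (default 1.3).
#' @param ahi_law within-band AHI law: `"geometric"` (default; truncated
#'   decay with rate `ahi_decay`, matching the right-skewed AHI
#'   distribution of referral cohorts) or `"uniform"` over the band's
#'   integers.
#' @param ahi_decay geometric decay rate per AHI unit (default 0.85).
#' @param schema the [variable_schema()] the cohort conforms to.
#' @param seed integer seed stored with the spec.
#' @return A validated `generator_spec` object.
#' @export
generator_spec <- function(n_osa, n_healthy,
                           phenotype_weights_osa, phenotype_weights_healthy,
                           variables, severity_mix, ahi_bands,
                           missing_rate,
                           missing_mechanism = c("MCAR", "MAR"),
                           mar_healthy_factor = 1.3,
                           ahi_law = c("geometric", "uniform"),
                           ahi_decay = 0.85,
                           schema = default_schema(),
                           seed = NULL) {
  missing_mechanism <- match.arg(missing_mechanism)
  ahi_law <- match.arg(ahi_law)
  stopifnot(ahi_decay > 0, ahi_decay <= 1)
  stopifnot(n_osa >= 0, n_healthy >= 0)
  if (!is_simplex(phenotype_weights_osa) ||
      !is_simplex(phenotype_weights_healthy)) {
    stop("phenotype weights must each sum to 1")
  }
  if (!all(abs(rowSums(severity_mix) - 1) <= 1e-9)) {
    stop("severity mix rows must sum to 1")
  }
  stopifnot_prob(missing_rate, "missing rates")
  if (!setequal(names(variables), schema$name)) {
    stop("variables must match the schema exactly")
  }
  for (v in schema$name) {
    ncat <- length(schema_categories(schema, v))
    for (side in c("osa", "healthy")) {
      m <- variables[[v]][[side]]
      if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != ncat ||
          !all(abs(rowSums(m) - 1) <= 1e-9)) {
        stop("bad category distribution for ", v, " (", side, ")")
      }
    }
  }
  bands <- ahi_bands[c("normal", "mild", "moderate", "severe")]
  edges <- unlist(bands)
  if (any(diff(edges) < 0) ||
      any(vapply(bands, function(b) b[1] > b[2], logical(1)))) {
    stop("ahi bands must be disjoint, ordered integer intervals")
  }
  structure(list(n_osa = as.integer(n_osa),
                 n_healthy = as.integer(n_healthy),
                 phenotype_weights_osa = phenotype_weights_osa,
                 phenotype_weights_healthy = phenotype_weights_healthy,
                 variables = variables,
                 severity_mix = severity_mix,
                 ahi_bands = bands,
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 mar_healthy_factor = mar_healthy_factor,
                 ahi_law = ahi_law,
                 ahi_decay = ahi_decay,
                 schema = schema,
                 seed = seed),
            class = "generator_spec")
}

phenotype_levels <- c("low", "medium", "high")
severity_levels <- c("normal", "mild", "moderate", "severe")

# 3-row probability matrix from per-phenotype "yes" probabilities.
.binary_rows <- function(p_low, p_med, p_high) {
  p <- c(p_low, p_med, p_high)
  cbind(no = 1 - p, yes = p)
}

#' Default generator specification
#'
#' Parameterized after the published referral-cohort descriptives: 207 OSA /
#' 111 healthy patients; OSA phenotype weights (74, 104, 29)/207 and healthy
#' weights (25, 79, 7)/111; per-variable category probabilities from the
#' published per-cluster frequency tables (OSA and healthy cohorts); the
#' severity mixture per phenotype from the per-cluster AHI rows; and
#' per-variable missingness from the published missing-data column. The four
#' screening-only symptom variables, absent from the cluster tables, get
#' status-conditional probabilities (identical across phenotypes).
#'
#' @param seed integer seed stored in the spec (default `NULL`).
#' @param missing_mechanism `"MCAR"` (default) or `"MAR"`.
#' @return A [generator_spec()].
#' @export
default_generator_spec <- function(seed = NULL,
                                   missing_mechanism = "MCAR") {
  schema <- default_schema()
  # Multi-category variables: counts per phenotype (rows low/medium/high).
  prob3 <- function(counts) sweep(counts, 1, rowSums(counts), "/")
  vars <- list(
    gender = list(
      osa = prob3(rbind(c(23, 51), c(32, 72), c(5, 24))),
      healthy = prob3(rbind(c(15, 10), c(40, 39), c(5, 2)))),
    age = list(
      osa = prob3(rbind(c(6, 46, 22), c(12, 59, 33), c(0, 7, 22))),
      healthy = prob3(rbind(c(16, 7, 2), c(15, 47, 17), c(0, 2, 5)))),
    bmi = list(
      osa = prob3(rbind(c(13, 15, 46), c(3, 50, 51), c(0, 9, 20))),
      healthy = prob3(rbind(c(4, 11, 10), c(6, 40, 33), c(1, 2, 4)))),
    nonrepairing_sleep = list(
      osa = .binary_rows(34 / 74, 57 / 104, 10 / 29),
      healthy = .binary_rows(18 / 25, 51 / 79, 3 / 7)),
    nocturia = list(
      osa = .binary_rows(14 / 74, 1, 1),
      healthy = .binary_rows(0, 54 / 79, 6 / 7)),
    stroke = list(
      osa = .binary_rows(34 / 74, 88 / 104, 27 / 29),
      healthy = .binary_rows(1 / 25, 66 / 79, 6 / 7)),
    arterial_hypertension = list(
      osa = .binary_rows(54 / 74, 96 / 104, 1),
      healthy = .binary_rows(14 / 25, 78 / 79, 1)),
    pulmonary_hypertension = list(
      osa = .binary_rows(9 / 74, 2 / 104, 6 / 29),
      healthy = .binary_rows(0, 1 / 79, 2 / 7)),
    congestive_heart_failure = list(
      osa = .binary_rows(4 / 74, 1 / 104, 23 / 29),
      healthy = .binary_rows(0, 0, 1)),
    arrhythmias = list(
      osa = .binary_rows(4 / 74, 1 / 104, 12 / 29),
      healthy = .binary_rows(0, 1 / 79, 2 / 7)),
    pacemaker = list(
      osa = .binary_rows(0, 4 / 104, 6 / 29),
      healthy = .binary_rows(0, 1 / 79, 0)),
    respiratory_changes = list(
      osa = .binary_rows(35 / 74, 28 / 104, 18 / 29),
      healthy = .binary_rows(7 / 25, 34 / 79, 5 / 7)),
    diabetes = list(
      osa = .binary_rows(37 / 74, 69 / 104, 1),
      healthy = .binary_rows(0, 55 / 79, 1)),
    dyslipidemia = list(
      osa = .binary_rows(57 / 74, 94 / 104, 1),
      healthy = .binary_rows(16 / 25, 75 / 79, 6 / 7)),
    # Screening-only symptoms: status-conditional, constant across
    # phenotypes. OSA-side values from the cohort totals; healthy-side
    # values are the generator's own choice (see the methods vignette).
    daytime_sleepiness = list(
      osa = .binary_rows(0.553, 0.553, 0.553),
      healthy = .binary_rows(0.50, 0.50, 0.50)),
    snoring = list(
      osa = .binary_rows(0.930, 0.930, 0.930),
      healthy = .binary_rows(0.85, 0.85, 0.85)),
    witnessed_apneas = list(
      osa = .binary_rows(0.645, 0.645, 0.645),
      healthy = .binary_rows(0.40, 0.40, 0.40)),
    gasping_choking = list(
      osa = .binary_rows(0.435, 0.435, 0.435),
      healthy = .binary_rows(0.30, 0.30, 0.30))
  )
  severity_mix <- rbind(low = c(51, 18, 5) / 74,
                        medium = c(54, 24, 26) / 104,
                        high = c(6, 8, 15) / 29)
  colnames(severity_mix) <- c("mild", "moderate", "severe")
  missing_rate <- c(
    gender = 0, age = 0, bmi = 0.184,
    nonrepairing_sleep = 0.116, nocturia = 0.343,
    stroke = 0.787, arterial_hypertension = 0.232,
    pulmonary_hypertension = 0.435, congestive_heart_failure = 0.333,
    arrhythmias = 0.522, pacemaker = 0.560,
    respiratory_changes = 0.106, diabetes = 0.522, dyslipidemia = 0.285,
    daytime_sleepiness = 0.048, snoring = 0.029,
    witnessed_apneas = 0.184, gasping_choking = 0.256)
  generator_spec(
    n_osa = 207, n_healthy = 111,
    phenotype_weights_osa = c(74, 104, 29) / 207,
    phenotype_weights_healthy = c(25, 79, 7) / 111,
    variables = vars,
    severity_mix = severity_mix,
    ahi_bands = list(normal = c(0L, 4L), mild = c(5L, 14L),
                     moderate = c(15L, 29L), severe = c(30L, 120L)),
    missing_rate = missing_rate,
    missing_mechanism = missing_mechanism,
    schema = schema,
    seed = seed)
}

#' Generate a complete synthetic cohort
#'
#' Draws `n_osa + n_healthy` records: the latent phenotype from the
#' status-specific mixture, every predictor from its (phenotype, status)
#' category distribution, then severity from the phenotype's mixture (OSA)
#' or `normal` (healthy) and an integer AHI uniformly within the severity
#' band. The latent phenotype is kept as hidden ground truth.
#'
#' @param spec a [generator_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A complete [osa_cohort()] (no missing cells).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_osa + spec$n_healthy
  if (n == 0L) stop("empty cohort requested")
  with_seed(seed, {
    osa <- sample(rep(c(1L, 0L), c(spec$n_osa, spec$n_healthy)))
    phen <- character(n)
    for (s in c(1L, 0L)) {
      idx <- which(osa == s)
      w <- if (s == 1L) spec$phenotype_weights_osa else
        spec$phenotype_weights_healthy
      phen[idx] <- sample(phenotype_levels, length(idx), TRUE, prob = w)
    }
    d <- data.frame(id = sprintf("P%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
    for (v in spec$schema$name) {
      cats <- schema_categories(spec$schema, v)
      col <- character(n)
      for (s in c(1L, 0L)) {
        pm <- spec$variables[[v]][[if (s == 1L) "osa" else "healthy"]]
        for (ph in seq_along(phenotype_levels)) {
          idx <- which(osa == s & phen == phenotype_levels[ph])
          if (length(idx)) {
            col[idx] <- sample(cats, length(idx), TRUE, prob = pm[ph, ])
          }
        }
      }
      d[[v]] <- col
    }
    sev <- character(n)
    sev[osa == 0L] <- "normal"
    for (ph in seq_along(phenotype_levels)) {
      idx <- which(osa == 1L & phen == phenotype_levels[ph])
      if (length(idx)) {
        sev[idx] <- sample(colnames(spec$severity_mix), length(idx), TRUE,
                           prob = spec$severity_mix[ph, ])
      }
    }
    ahi <- integer(n)
    for (lv in severity_levels) {
      idx <- which(sev == lv)
      if (length(idx)) {
        b <- spec$ahi_bands[[lv]]
        support <- seq.int(b[1], b[2])
        pr <- if (identical(spec$ahi_law, "uniform")) {
          rep(1, length(support))
        } else {
          spec$ahi_decay^(support - b[1])
        }
        ahi[idx] <- sample(support, length(idx), TRUE, prob = pr)
      }
    }
    d$ahi <- ahi
    d$severity <- sev
    d$osa <- osa
    osa_cohort(d, spec$schema, truth = list(phenotype = phen))
  })
}

#' Mask predictor values according to the spec's missingness model
#'
#' Each predictor entry is masked independently with its variable's rate
#' (MCAR), or with the rate multiplied by `mar_healthy_factor` for healthy
#' patients (MAR). The outcome columns are never masked; pre-masking values
#' are retained as hidden truth so imputation can be scored.
#'
#' @param cohort a complete [osa_cohort()].
#' @param spec a [generator_spec()].
#' @param seed overrides `spec$seed` when given (offset so that masking is
#'   not correlated with generation draws).
#' @return The masked cohort, with `truth$complete` filled in.
#' @export
inject_missingness <- function(cohort, spec,
                               seed = if (is.null(spec$seed)) NULL else
                                 spec$seed + 1L) {
  stopifnot_prob(spec$missing_rate, "missing rates")
  d <- cohort$data
  complete <- d[spec$schema$name]
  with_seed(seed, {
    for (v in spec$schema$name) {
      rate <- rep(spec$missing_rate[[v]], nrow(d))
      if (spec$missing_mechanism == "MAR") {
        rate[d$osa == 0L] <- pmin(1, rate[d$osa == 0L] *
                                    spec$mar_healthy_factor)
      }
      mask <- stats::runif(nrow(d)) < rate
      d[[v]][mask] <- NA_character_
    }
  })
  truth <- cohort$truth %||% list()
  truth$complete <- complete
  osa_cohort(d, cohort$schema, truth = truth)
}

#' Serialize a generator spec to / from JSON
#'
#' @param spec a [generator_spec()].
#' @param path file path.
#' @return `write_generator_spec` returns `path` invisibly;
#'   `read_generator_spec` returns a validated [generator_spec()].
#' @export
write_generator_spec <- function(spec, path) {
  x <- unclass(spec)
  x$schema <- list(name = spec$schema$name,
                   categories = spec$schema$categories,
                   role = spec$schema$role,
                   severe_level = spec$schema$severe_level,
                   exclusion_flag = spec$schema$exclusion_flag)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- variable_schema(name = x$schema$name,
                            categories = x$schema$categories,
                            role = x$schema$role,
                            severe_level = x$schema$severe_level,
                            exclusion_flag = x$schema$exclusion_flag)
  vars <- lapply(x$variables, function(v) {
    list(osa = as.matrix(v$osa), healthy = as.matrix(v$healthy))
  })
  sev <- as.matrix(x$severity_mix)
  dimnames(sev) <- list(phenotype_levels, c("mild", "moderate", "severe"))
  generator_spec(
    n_osa = x$n_osa, n_healthy = x$n_healthy,
    phenotype_weights_osa = unlist(x$phenotype_weights_osa),
    phenotype_weights_healthy = unlist(x$phenotype_weights_healthy),
    variables = vars, severity_mix = sev,
    ahi_bands = lapply(x$ahi_bands, as.integer),
    missing_rate = unlist(x$missing_rate),
    missing_mechanism = x$missing_mechanism,
    mar_healthy_factor = x$mar_healthy_factor,
    ahi_law = x$ahi_law, ahi_decay = x$ahi_decay,
    schema = schema, seed = x$seed)
}
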