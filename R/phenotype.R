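#' Crude odds ratio of a variable for severe OSA
#'
#' Cross-product odds ratio of the 2x2 table (variable at its exposed level
#' vs the rest) x (severe vs non-severe), computed among OSA patients.
#' Multi-category variables are binarized at the schema's `severe_level`
#' category (e.g. obese vs non-obese). Zero cells receive the
#' Haldane-Anscombe +0.5 correction in every cell.
#'
#' @param cohort an imputed [osa_cohort()] (OSA patients are subset
#'   internally).
#' @param variable variable name.
#' @return Positive finite odds ratio, or `NA` with a warning when the
#'   variable is constant.
#' @export
crude_or_severe <- function(cohort, variable) {
  d <- cohort$data[cohort$data$osa == 1L, ]
  lvl <- cohort$schema$severe_level[match(variable, cohort$schema$name)]
  if (is.na(lvl)) stop("unknown variable: ", variable)
  x <- d[[variable]]
  if (anyNA(x)) stop("crude_or_severe requires imputed (complete) data")
  exposed <- x == lvl
  severe <- d$severity == "severe"
  if (length(unique(exposed)) < 2L) {
    warning("variable ", variable, " is constant; weight undefined")
    return(NA_real_)
  }
  a <- sum(exposed & severe)      # severe, exposed
  b <- sum(!exposed & severe)     # severe, unexposed
  c_ <- sum(exposed & !severe)
  d_ <- sum(!exposed & !severe)
  if (min(a, b, c_, d_) == 0L) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d_ <- d_ + 0.5
  }
  (a * d_) / (b * c_)
}

#' Odds-ratio weights for a set of cluster variables
#'
#' @param cohort an imputed [osa_cohort()].
#' @param variables character vector of selected variables.
#' @return Named numeric weight vector; constant variables are dropped with
#'   a warning.
#' @export
compute_weights <- function(cohort, variables) {
  w <- vapply(variables, function(v) crude_or_severe(cohort, v), numeric(1))
  w[!is.na(w)]
}

#' Odds-ratio-weighted mismatch distance between two patients
#'
#' `d(a, b) = sum_j w_j * 1[a_j != b_j]` over the weighted variables: a
#' weighted Hamming pseudo-metric on the selected categorical space. With
#' `normalize = TRUE` the sum is divided by `sum(w)`.
#'
#' @param a,b named character vectors (or single-row data frames) holding
#'   the selected variables; no missing values allowed.
#' @param w named weight vector from [compute_weights()].
#' @param normalize divide by the total weight (default `FALSE`).
#' @return Non-negative distance.
#' @export
patient_distance <- function(a, b, w, normalize = FALSE) {
  a <- unlist(a[names(w)])
  b <- unlist(b[names(w)])
  if (anyNA(a) || anyNA(b)) stop("missing value on a selected variable")
  d <- sum(w * (a != b))
  if (normalize) d <- d / sum(w)
  d
}

#' Pairwise weighted-mismatch distance matrix
#'
#' @param data data frame of selected-variable values (complete).
#' @param w named weight vector.
#' @param normalize divide by the total weight.
#' @return Symmetric zero-diagonal numeric matrix.
#' @export
distance_matrix <- function(data, w, normalize = FALSE) {
  n <- nrow(data)
  dm <- matrix(0, n, n)
  for (v in names(w)) {
    x <- data[[v]]
    if (anyNA(x)) stop("missing value on selected variable ", v)
    dm <- dm + w[[v]] * outer(x, x, "!=")
  }
  if (normalize) dm <- dm / sum(w)
  dm
}

# Weighted-mismatch distances from each query row to each reference row.
.cross_distance <- function(query, reference, w, normalize = FALSE) {
  out <- matrix(0, nrow(query), nrow(reference))
  for (v in names(w)) {
    qx <- query[[v]]
    rx <- reference[[v]]
    if (anyNA(qx) || anyNA(rx)) {
      stop("missing value on selected variable ", v)
    }
    out <- out + w[[v]] * outer(qx, rx, "!=")
  }
  if (normalize) out <- out / sum(w)
  out
}

#' Ward dendrogram from a distance matrix
#'
#' Agglomerates by the Lance-Williams Ward update applied to the supplied
#' (non-squared) dissimilarities — the classic `"ward.D"` convention
#' ([stats::hclust()]); `"ward.D2"` is available via `method`.
#'
#' @param dm symmetric, zero-diagonal, non-negative distance matrix,
#'   n >= 2.
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return An [stats::hclust] object.
#' @export
ward_dendrogram <- function(dm, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  if (!is.matrix(dm) || nrow(dm) < 2L) stop("need an n >= 2 distance matrix")
  if (anyNA(dm) || any(!is.finite(dm)) || any(dm < 0)) {
    stop("distances must be finite and non-negative")
  }
  if (max(abs(dm - t(dm))) > 1e-8 || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with a zero diagonal")
  }
  stats::hclust(stats::as.dist(dm), method = method)
}

# Exact 1-D 3-means on a short vector: the optimal partition is contiguous
# in sorted order, so enumerate the two breakpoints.
.kmeans1d3 <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  best <- NULL
  best_ss <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      g <- rep(1:3, c(i, j - i, n - j))
      ss <- sum(tapply(xs, g, function(v) sum((v - mean(v))^2)))
      if (ss < best_ss - 1e-12) {
        best_ss <- ss
        best <- g
      }
    }
  }
  out <- integer(n)
  out[ord] <- best
  out
}

#' Cut the dendrogram and aggregate fine clusters into 3 phenotypes
#'
#' Cuts into `k_fine` clusters, computes each fine cluster's median AHI,
#' groups the fine clusters by exact 1-D 3-means on those medians, and
#' labels the groups low / medium / high by ascending pooled median AHI.
#' With fewer than 3 distinct medians the grouping falls back to a tertile
#' split with a warning.
#'
#' @param hc dendrogram from [ward_dendrogram()] over OSA patients.
#' @param ahi integer AHI per clustered patient.
#' @param k_fine number of fine clusters (default 10).
#' @return List with `fine_labels`, `fine_medians`, `aggregation_map`
#'   (fine cluster -> phenotype) and `phenotype` per patient.
#' @export
cut_and_aggregate <- function(hc, ahi, k_fine = 10) {
  n <- length(hc$order)
  if (k_fine > n) stop("k_fine exceeds the number of patients")
  fine <- stats::cutree(hc, k = k_fine)
  med <- tapply(ahi, fine, stats::median)
  if (k_fine <= 3L) {
    grp <- seq_len(k_fine)
  } else if (length(unique(med)) < 3L) {
    warning("fewer than 3 distinct fine-cluster medians; tertile fallback")
    grp <- as.integer(cut(rank(med, ties.method = "first"),
                          breaks = 3, labels = FALSE))
  } else {
    grp <- .kmeans1d3(as.numeric(med))
  }
  # Order groups low/medium/high by pooled median AHI.
  pooled <- vapply(1:max(grp), function(g) {
    stats::median(ahi[fine %in% as.integer(names(med))[grp == g]])
  }, numeric(1))
  lab <- phenotype_levels[seq_along(pooled)][order(order(pooled))]
  map <- stats::setNames(lab[grp], names(med))
  phenotype <- unname(map[as.character(fine)])
  list(fine_labels = fine,
       fine_medians = med,
       aggregation_map = map,
       phenotype = phenotype)
}

#' Fit the full phenotype model on an imputed cohort
#'
#' Runs the phenotyping chain on the OSA subcohort: crude-OR weights for
#' the selected variables, the weighted-mismatch distance matrix, Ward
#' clustering, the fine cut, and the 10-to-3 median-AHI aggregation. The
#' clustered OSA records are stored as reference patients for affinity
#' assignment.
#'
#' @param cohort an imputed [osa_cohort()] containing OSA patients.
#' @param variables selected cluster variables (see
#'   [select_cluster_variables()]).
#' @param k_fine fine cut size (default 10).
#' @param method Ward variant (see [ward_dendrogram()]).
#' @param normalize normalize distances by total weight.
#' @return A `phenotype_model` object.
#' @export
fit_phenotypes <- function(cohort, variables, k_fine = 10,
                           method = "ward.D", normalize = FALSE) {
  osa <- cohort$data[cohort$data$osa == 1L, ]
  w <- compute_weights(cohort, variables)
  dm <- distance_matrix(osa[names(w)], w, normalize = normalize)
  hc <- ward_dendrogram(dm, method = method)
  agg <- cut_and_aggregate(hc, osa$ahi, k_fine = k_fine)
  structure(list(weights = w,
                 variables = names(w),
                 dendrogram = hc,
                 fine_labels = agg$fine_labels,
                 fine_medians = agg$fine_medians,
                 aggregation_map = agg$aggregation_map,
                 phenotype = agg$phenotype,
                 reference = cbind(osa[c("id", "ahi")],
                                   osa[names(w)],
                                   phenotype = agg$phenotype),
                 normalize = normalize,
                 method = method),
            class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  tab <- table(factor(x$phenotype, levels = phenotype_levels))
  cat(sprintf(
    "phenotype_model: %d reference patients, %d weighted variables\n",
    nrow(x$reference), length(x$weights)))
  cat("  phenotypes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  fine-cluster median AHI:",
      paste(sort(as.numeric(x$fine_medians)), collapse = ", "), "\n")
  invisible(x)
}

#' Assign patients to the closest phenotype
#'
#' Affinity of a patient to each phenotype is the mean weighted-mismatch
#' distance to that phenotype's reference patients (with
#' `affinity = "medoid"`, the distance to the phenotype medoid). The
#' assigned phenotype minimizes affinity; exact ties break toward the
#' lower-severity phenotype (conservative for rule-out screening).
#'
#' @param newdata data frame of records complete on the model's variables
#'   (need not be OSA patients).
#' @param model a [fit_phenotypes()] model.
#' @param affinity `"mean"` (default) or `"medoid"`.
#' @return Data frame with `phenotype` and one affinity column per
#'   phenotype.
#' @export
assign_phenotype <- function(newdata, model,
                             affinity = c("mean", "medoid")) {
  affinity <- match.arg(affinity)
  ref <- model$reference
  aff <- sapply(phenotype_levels, function(ph) {
    members <- ref[ref$phenotype == ph, model$variables, drop = FALSE]
    if (!nrow(members)) stop("empty reference cluster: ", ph)
    dd <- .cross_distance(newdata[model$variables], members, model$weights,
                          normalize = model$normalize)
    if (affinity == "mean") {
      rowMeans(dd)
    } else {
      within <- .cross_distance(members, members, model$weights,
                                normalize = model$normalize)
      dd[, which.min(rowMeans(within)), drop = TRUE]
    }
  })
  aff <- matrix(aff, ncol = 3,
                dimnames = list(NULL, phenotype_levels))
  # which.max/min take the first index on ties; columns are ordered
  # low, medium, high, so ties already fall to the lower severity.
  pick <- apply(aff, 1L, which.min)
  data.frame(phenotype = phenotype_levels[pick],
             affinity_low = aff[, "low"],
             affinity_medium = aff[, "medium"],
             affinity_high = aff[, "high"],
             stringsAsFactors = FALSE)
}

#' Describe phenotypes with exact binomial intervals
#'
#' Per phenotype and variable category: count, proportion and the
#' Clopper-Pearson exact 95% CI; plus each phenotype's severity
#' distribution and median AHI (attributes `severity` and `median_ahi`).
#'
#' @param cohort an imputed [osa_cohort()].
#' @param model a [fit_phenotypes()] model.
#' @param phenotype phenotype label per cohort row; defaults to the model's
#'   reference labels when `cohort` is the clustered OSA subcohort,
#'   otherwise supply [assign_phenotype()] output.
#' @return Data frame with one row per (phenotype, variable, category).
#' @export
describe_clusters <- function(cohort, model, phenotype = NULL) {
  d <- cohort$data
  if (is.null(phenotype)) {
    idx <- match(d$id, model$reference$id)
    if (anyNA(idx)) {
      stop("cohort rows not in the reference set; supply `phenotype`")
    }
    phenotype <- model$reference$phenotype[idx]
  }
  rows <- list()
  for (ph in phenotype_levels) {
    sub <- d[phenotype == ph, , drop = FALSE]
    for (v in model$variables) {
      for (cat in schema_categories(cohort$schema, v)) {
        x <- sum(sub[[v]] == cat)
        ci <- proportion_ci(x, nrow(sub))
        rows[[length(rows) + 1L]] <- data.frame(
          phenotype = ph, variable = v, category = cat,
          n = nrow(sub), count = x, proportion = x / nrow(sub),
          ci_lower = ci[1], ci_upper = ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "severity") <- table(phenotype, d$severity)
  attr(out, "median_ahi") <- tapply(d$ahi, phenotype, stats::median)
  out
}

#' Export a phenotype model to JSON / its dendrogram to Newick
#'
#' @param model a [fit_phenotypes()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype_model <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model$weights),
         variables = model$variables,
         merge = model$dendrogram$merge,
         height = model$dendrogram$height,
         fine_labels = unname(model$fine_labels),
         fine_medians = as.list(model$fine_medians),
         aggregation_map = as.list(model$aggregation_map),
         phenotype = model$phenotype,
         reference_ids = model$reference$id,
         normalize = model$normalize,
         method = model$method),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
dendrogram_newick <- function(model, path = NULL) {
  hc <- model$dendrogram
  hc$labels <- model$reference$id
  tree <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(path)
  }
}
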