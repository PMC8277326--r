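test_that("ROC/AUC handles separation, ties and the null case", {
  roc <- roc_and_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  # hand-listed scores with one tie: oracle is the pairwise count
  s <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  l <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_and_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  # scores independent of labels at large n: AUC near 1/2
  set.seed(10)
  s2 <- stats::runif(4000); l2 <- stats::rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_and_auc(s2, l2)$auc - 0.5), 0.03)
  expect_error(roc_and_auc(c(1, 2), c(1, 1)), "one positive and one negative")
})

test_that("trapezoid AUC equals the Mann-Whitney count on random sets", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    s <- round(stats::runif(n), 2)  # rounding forces ties
    l <- stats::rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(roc_and_auc(s, l)$auc, oracle_auc(s, l),
                 tolerance = 1e-12)
  }
})

test_that("ROC is a monotone step function from (0,0) to (1,1)", {
  set.seed(13)
  s <- stats::runif(200); l <- stats::rbinom(200, 1, 0.6)
  pts <- roc_and_auc(s, l)$points
  ord <- order(pts$threshold)
  # sensitivity falls, specificity rises as the threshold rises
  expect_true(all(diff(pts$sens[ord]) <= 1e-12))
  expect_true(all(diff(pts$spec[ord]) >= -1e-12))
  expect_equal(range(pts$sens), c(0, 1))
  expect_equal(range(pts$spec), c(0, 1))
})

test_that("cutoff selection returns the largest threshold meeting target", {
  # sens = 1 up to 11%, 0.99 up to 22%, 0.94 up to 89%
  pos <- c(rep(0.9, 94), rep(0.23, 5), 0.115)
  neg <- rep(0.05, 50)
  roc <- roc_and_auc(c(pos, neg), rep(c(1, 0), c(100, 50)))
  expect_identical(choose_cutoff(roc, 0.95), 22L)
  # target 1: must sit below the minimum positive score
  expect_lt(choose_cutoff(roc, 1) / 100, min(pos))
  # degenerate all-equal scores: the single informative threshold (just
  # below the common score) is returned
  roc2 <- roc_and_auc(rep(0.4, 10), rep(c(1, 0), 5))
  expect_identical(choose_cutoff(roc2, 0.95), 39L)
  # an unreachable target warns and falls back to the lowest threshold
  roc3 <- roc_and_auc(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_warning(c3 <- choose_cutoff(roc3, 0.95), "no cutoff")
  expect_identical(c3, 0L)
})

test_that("lowering the cutoff never hurts sensitivity nor helps specificity", {
  set.seed(17)
  s <- stats::runif(300); l <- stats::rbinom(300, 1, 0.6)
  sens <- spec <- numeric(101)
  for (t in 0:100) {
    pred <- s > t / 100
    sens[t + 1] <- mean(pred[l == 1])
    spec[t + 1] <- mean(!pred[l == 0])
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("the metric panel reproduces the printed effectiveness figures", {
  # sens 91% / spec 26% and sens 93% / spec 38% at n = 100 per margin
  a <- diagnostic_metrics(tp = 91, fn = 9, tn = 26, fp = 74)
  expect_equal(a$dor, 3.55, tolerance = 5e-3)
  b <- diagnostic_metrics(tp = 93, fn = 7, tn = 38, fp = 62)
  expect_equal(b$dor, 8.14, tolerance = 5e-3)
  # internal identities
  expect_equal(a$dor, a$lr_pos / a$lr_neg, tolerance = 1e-9)
  expect_equal(a$dor, (91 * 26) / (74 * 9), tolerance = 1e-9)
  # balanced counts: an uninformative test
  u <- diagnostic_metrics(tp = 20, fn = 20, tn = 30, fp = 30)
  expect_equal(u$sensitivity, 0.5)
  expect_equal(u$specificity, 0.5)
  expect_equal(u$dor, 1)
  # zero cell: Haldane correction keeps DOR finite
  z <- diagnostic_metrics(tp = 10, fn = 0, tn = 5, fp = 5)
  expect_true(is.finite(z$dor))
  expect_error(diagnostic_metrics(0, 0, 0, 0), "margin")
})

test_that("DOR identity holds on random confusion tables", {
  set.seed(19)
  for (i in 1:100) {
    k <- sample(1:50, 4, replace = TRUE)
    m <- diagnostic_metrics(k[1], k[2], k[3], k[4])
    expect_equal(m$dor, m$lr_pos / m$lr_neg, tolerance = 1e-9)
    expect_equal(m$dor, (k[1] * k[3]) / (k[2] * k[4]), tolerance = 1e-9)
    expect_true(all(unlist(m[c("sensitivity", "specificity", "accuracy",
                               "ppv", "npv")]) >= 0))
  }
})

test_that("posttest probabilities follow the Fagan odds chain", {
  # printed model-A values at 65% pretest probability (printed odds carry
  # two decimals, so agreement is asserted to 0.011)
  pa <- posttest(0.65, 1.32)
  expect_lt(abs(pa$posttest_odds - 2.45), 0.011)
  expect_equal(round(100 * pa$posttest_probability), 71)
  na <- posttest(0.65, 0.17)
  expect_lt(abs(na$posttest_odds - 0.32), 0.011)
  # printed model-B values
  pb <- posttest(0.65, 1.63)
  expect_lt(abs(pb$posttest_odds - 3.02), 0.011)
  expect_equal(round(100 * pb$posttest_probability), 75)
  nb <- posttest(0.65, 0.12)
  expect_lt(abs(nb$posttest_odds - 0.22), 0.011)
  expect_equal(round(100 * nb$posttest_probability), 18)
  # identity at LR = 1 and monotonicity in LR
  for (p in c(0.2, 0.5, 0.65)) {
    expect_equal(posttest(p, 1)$posttest_probability, p, tolerance = 1e-12)
  }
  lrs <- c(0.1, 0.5, 1, 2, 10)
  post <- vapply(lrs, function(l) posttest(0.3, l)$posttest_probability,
                 numeric(1))
  expect_true(all(diff(post) > 0))
  expect_error(posttest(1, 2), "strictly inside")
  expect_error(posttest(0.5, 0), "positive")
})

test_that("the symptom rule needs sleepiness plus two supporting criteria", {
  d <- data.frame(
    daytime_sleepiness = c("no", "yes", "yes", "yes", NA),
    snoring = c("yes", "yes", "yes", "yes", "yes"),
    witnessed_apneas = c("yes", "no", "no", "yes", "yes"),
    gasping_choking = c("yes", "no", "no", "no", "no"),
    arterial_hypertension = c("yes", "yes", "no", "no", "yes"))
  flag <- aasm_rule(d)
  expect_identical(as.logical(flag), c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(attr(flag, "missing_ingredient"),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(aasm_rule(d[, -1]), "missing columns")
})

test_that("cross-validation schemes are deterministic and well-formed", {
  spec <- default_generator_spec(seed = 51)
  spec$n_osa <- 60L; spec$n_healthy <- 40L
  spec$missing_rate[] <- 0
  co <- generate_cohort(spec)
  vars <- c("nocturia", "stroke", "diabetes", "age")
  r1 <- suppressWarnings(
    cross_validate(co, "A", scheme = "10x2cv", seed = 5,
                   cluster_vars = vars))
  r2 <- suppressWarnings(
    cross_validate(co, "A", scheme = "10x2cv", seed = 5,
                   cluster_vars = vars))
  expect_identical(r1$rep_auc, r2$rep_auc)
  expect_identical(r1$metrics$sensitivity, r2$metrics$sensitivity)
  expect_length(r1$rep_auc, 10)
  expect_length(r1$fold_metrics, 20)
  loo <- suppressWarnings(
    cross_validate(co, "A", scheme = "loo", seed = 5,
                   cluster_vars = vars))
  expect_length(loo$scores, 100)
  expect_s3_class(loo$metrics, "diagnostic_metrics")
  # model B runs the fold-refit phenotyping path
  rb <- suppressWarnings(
    cross_validate(co, "B", scheme = "10x2cv", seed = 5,
                   cluster_vars = vars, k_fine = 5))
  expect_true(rb$auc > 0 && rb$auc < 1)
  tf <- tempfile(fileext = ".json")
  write_validation_report(rb, tf)
  expect_true(jsonlite::validate(paste(readLines(tf), collapse = "")))
})

test_that("metric intervals tighten with more repetitions", {
  spec <- default_generator_spec(seed = 61)
  spec$n_osa <- 90L; spec$n_healthy <- 60L
  spec$missing_rate[] <- 0
  vars <- c("nocturia", "stroke", "diabetes", "age")
  width <- function(reps, seeds) {
    mean(vapply(seeds, function(s) {
      co <- generate_cohort(spec)
      r <- suppressWarnings(
        cross_validate(co, "A", seed = s, cluster_vars = vars,
                       reps = reps))
      diff(r$metrics$accuracy$ci)
    }, numeric(1)))
  }
  expect_lt(width(10, 1:8), width(2, 1:8))
})
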