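test_that("crude odds ratios reproduce the printed nocturia cross-product", {
  # severe: 32 yes / 2 no; non-severe: 67 yes / 35 no
  sev <- rep(c("severe", "mild"), c(34, 102))
  noc <- c(rep(c("yes", "no"), c(32, 2)), rep(c("yes", "no"), c(67, 35)))
  co <- build_cohort(data.frame(nocturia = noc), ahi = ahi_for(sev))
  expect_equal(crude_or_severe(co, "nocturia"), (32 * 35) / (2 * 67),
               tolerance = 1e-9)
})

test_that("odds-ratio corner cases behave", {
  sev <- rep(c("severe", "mild"), each = 40)
  # identical distribution in both outcome groups: OR = 1
  eq <- rep(rep(c("yes", "no"), each = 20), 2)
  co <- build_cohort(data.frame(v = eq), ahi = ahi_for(sev))
  expect_equal(crude_or_severe(co, "v"), 1)
  # zero cell: Haldane-Anscombe correction keeps it finite
  zc <- c(rep("yes", 40), rep(c("yes", "no"), c(20, 20)))
  co2 <- build_cohort(data.frame(v = zc), ahi = ahi_for(sev))
  or <- crude_or_severe(co2, "v")
  expect_true(is.finite(or))
  expect_equal(or, (40.5 * 20.5) / (0.5 * 20.5), tolerance = 1e-9)
  # constant variable: undefined weight with warning
  co3 <- build_cohort(data.frame(v = rep("yes", 80)), ahi = ahi_for(sev))
  expect_warning(w <- crude_or_severe(co3, "v"), "constant")
  expect_true(is.na(w))
})

test_that("the weighted mismatch distance is a weighted Hamming form", {
  w <- c(a = 2, b = 1, c = 4)
  x <- c(a = "yes", b = "no", c = "yes")
  y <- c(a = "no", b = "no", c = "no")
  expect_equal(patient_distance(x, x, w), 0)
  expect_equal(patient_distance(x, y, w), 6)   # mismatch on a and c
  z <- c(a = "yes", b = "yes", c = "yes")
  expect_equal(patient_distance(x, z, w), 1)   # only b differs
  expect_equal(patient_distance(x, y, w), patient_distance(y, x, w))
  expect_equal(patient_distance(x, y, w, normalize = TRUE), 6 / 7)
  expect_error(patient_distance(c(a = NA, b = "no", c = "no"), y, w),
               "missing")
})

test_that("the distance satisfies the triangle inequality", {
  set.seed(12)
  vars <- paste0("v", 1:5)
  w <- stats::setNames(stats::runif(5, 0.2, 5), vars)
  for (i in 1:50) {
    tri <- matrix(sample(c("a", "b", "c"), 15, TRUE), nrow = 3,
                  dimnames = list(NULL, vars))
    d12 <- patient_distance(tri[1, ], tri[2, ], w)
    d13 <- patient_distance(tri[1, ], tri[3, ], w)
    d23 <- patient_distance(tri[2, ], tri[3, ], w)
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("Ward merges match the brute-force Lance-Williams recursion", {
  set.seed(3)
  for (i in 1:200) {
    n <- 6
    pts <- matrix(stats::rnorm(n * 2), n)
    dm <- as.matrix(stats::dist(pts))
    hc <- ward_dendrogram(dm)
    oracle <- oracle_ward_lw(dm)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-9)
    expect_identical(hclust_partitions(hc, n), oracle$partitions)
  }
})

test_that("a two-point dendrogram merges at the pairwise distance", {
  dm <- matrix(c(0, 3.2, 3.2, 0), 2)
  hc <- ward_dendrogram(dm)
  expect_equal(hc$height, 3.2)
})

test_that("well-separated blobs merge within themselves first", {
  set.seed(8)
  n <- 12
  pts <- c(stats::rnorm(6, 0, 0.1), stats::rnorm(6, 100, 0.1))
  dm <- as.matrix(stats::dist(pts))
  hc <- ward_dendrogram(dm)
  labs <- stats::cutree(hc, 2)
  expect_equal(length(unique(labs[1:6])), 1L)
  expect_equal(length(unique(labs[7:12])), 1L)
})

test_that("distances scale with the weights but the tree does not", {
  spec <- default_generator_spec(seed = 19)
  spec$n_osa <- 80L; spec$n_healthy <- 0L
  co <- generate_cohort(spec)
  vars <- c("nocturia", "stroke", "diabetes", "age")
  w <- compute_weights(co, vars)
  dm1 <- distance_matrix(co$data[names(w)], w)
  dm2 <- distance_matrix(co$data[names(w)], w * 7)
  expect_equal(dm2, dm1 * 7, tolerance = 1e-12)
  h1 <- ward_dendrogram(dm1); h2 <- ward_dendrogram(dm2)
  expect_identical(stats::cutree(h1, 10), stats::cutree(h2, 10))
  expect_equal(h2$height, h1$height * 7, tolerance = 1e-9)
})

test_that("fine clusters aggregate by their median AHI into 3 phenotypes", {
  # ten tight blobs whose AHI medians reproduce the published fine medians
  set.seed(14)
  meds <- c(8, 10, 10, 10, 10, 12, 13, 14, 31, 34)
  n_per <- 5
  centers <- seq(0, 900, by = 100)
  x <- rep(centers, each = n_per) + stats::runif(50, 0, 1)
  dm <- as.matrix(stats::dist(x))
  hc <- ward_dendrogram(dm)
  ahi <- rep(meds, each = n_per)
  agg <- cut_and_aggregate(hc, ahi, k_fine = 10)
  grouped <- split(as.numeric(agg$fine_medians), agg$aggregation_map)
  expect_identical(lapply(grouped[c("low", "medium", "high")], sort),
                   list(low = c(8, 10, 10, 10, 10),
                        medium = c(12, 13, 14), high = c(31, 34)))
  # labels respect pooled median order
  med_by_ph <- tapply(ahi, agg$phenotype, stats::median)
  expect_true(med_by_ph["low"] < med_by_ph["medium"])
  expect_true(med_by_ph["medium"] < med_by_ph["high"])
})

test_that("k_fine = 3 makes aggregation the identity", {
  set.seed(5)
  x <- c(stats::rnorm(5), stats::rnorm(5, 50), stats::rnorm(5, 100))
  dm <- as.matrix(stats::dist(x))
  agg <- cut_and_aggregate(ward_dendrogram(dm),
                           rep(c(8L, 20L, 40L), each = 5), k_fine = 3)
  expect_identical(sort(unique(agg$aggregation_map)),
                   c("high", "low", "medium"))
  expect_equal(length(unique(agg$fine_labels)), 3L)
})

test_that("affinity assignment picks the closest phenotype", {
  w <- c(a = 2, b = 1)
  ref <- data.frame(
    id = sprintf("r%d", 1:6), ahi = c(8L, 8L, 20L, 20L, 40L, 40L),
    a = c("no", "no", "no", "yes", "yes", "yes"),
    b = c("no", "no", "yes", "yes", "yes", "yes"),
    phenotype = rep(c("low", "medium", "high"), each = 2))
  m <- structure(list(weights = w, variables = c("a", "b"),
                      normalize = FALSE, reference = ref),
                 class = "phenotype_model")
  # identical to the high references, maximally distant from low
  asg <- assign_phenotype(data.frame(a = "yes", b = "yes"), m)
  expect_identical(asg$phenotype, "high")
  expect_equal(asg$affinity_high, 0)
  expect_equal(asg$affinity_low, 3)
  expect_equal(asg$affinity_medium, 1)  # mean of w_a and 0
  # ties break toward the lower-severity phenotype
  m <- structure(list(
    weights = c(v = 1), variables = "v", normalize = FALSE,
    reference = data.frame(id = c("r1", "r2", "r3"),
                           ahi = c(8L, 20L, 40L),
                           v = c("yes", "yes", "yes"),
                           phenotype = c("low", "medium", "high"))),
    class = "phenotype_model")
  tie <- assign_phenotype(data.frame(v = "no"), m)
  expect_identical(tie$phenotype, "low")
})

test_that("healthy patients drawn from high-phenotype conditionals go high", {
  spec <- default_generator_spec(seed = 29)
  co <- generate_cohort(spec)
  vars <- c("nocturia", "stroke", "congestive_heart_failure", "diabetes",
            "age", "arterial_hypertension", "arrhythmias")
  pm <- fit_phenotypes(co, vars)
  spec_h <- spec
  spec_h$seed <- 290L
  spec_h$n_osa <- 0L
  spec_h$n_healthy <- 300L
  spec_h$phenotype_weights_healthy <- c(0, 0, 1)
  hi <- generate_cohort(spec_h)
  asg <- assign_phenotype(hi$data, pm)
  expect_gt(mean(asg$phenotype == "high"), 0.5)
})

test_that("cluster descriptions carry exact binomial intervals", {
  spec <- default_generator_spec(seed = 33)
  co <- generate_cohort(spec)
  pm <- fit_phenotypes(co, c("nocturia", "stroke", "age"))
  osa <- osa_cohort(co$data[co$data$osa == 1, ], co$schema)
  tab <- describe_clusters(osa, pm)
  expect_true(all(tab$ci_lower >= 0 & tab$ci_upper <= 1))
  expect_true(all(tab$ci_lower <= tab$proportion + 1e-12))
  expect_true(all(tab$ci_upper >= tab$proportion - 1e-12))
  expect_false(is.null(attr(tab, "median_ahi")))
  # the printed-table interval identities (bounds print as truncated
  # integer percents)
  expect_identical(floor(proportion_ci(51, 74) * 100), c(57, 79))
  expect_identical(floor(proportion_ci(104, 104) * 100), c(96, 100))
  expect_identical(proportion_ci(0, 29)[1], 0)
})

test_that("phenotype models serialize to JSON and Newick", {
  spec <- default_generator_spec(seed = 35)
  co <- generate_cohort(spec)
  pm <- fit_phenotypes(co, c("nocturia", "stroke", "age"))
  tf <- tempfile(fileext = ".json")
  write_phenotype_model(pm, tf)
  x <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_identical(sort(names(x$weights)), sort(pm$variables))
  expect_equal(length(x$phenotype), nrow(pm$reference))
  nwk <- dendrogram_newick(pm)
  expect_match(nwk, "^\\(.*\\);$")
})
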