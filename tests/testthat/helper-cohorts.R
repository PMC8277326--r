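# Small cohort builders used across test files.

# Yes/no schema over the given variable names.
yn_schema <- function(vars, exclusion = rep(FALSE, length(vars))) {
  variable_schema(vars,
                  categories = rep(list(c("no", "yes")), length(vars)),
                  role = "history",
                  severe_level = rep("yes", length(vars)),
                  exclusion_flag = exclusion)
}

# Cohort from a data frame of predictor values plus an ahi vector.
build_cohort <- function(values, ahi, schema = yn_schema(names(values))) {
  d <- data.frame(id = sprintf("T%03d", seq_len(nrow(values))),
                  values,
                  ahi = as.integer(ahi),
                  severity = classify_ahi(ahi),
                  osa = as.integer(ahi >= 5),
                  stringsAsFactors = FALSE)
  osa_cohort(d, schema)
}

# AHI values realizing given severity labels.
ahi_for <- function(severity) {
  unname(c(normal = 2L, mild = 10L, moderate = 20L, severe = 35L)[severity])
}

# Random yes/no values with given probability of "yes".
ryn <- function(n, p) c("no", "yes")[1 + stats::rbinom(n, 1, p)]
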