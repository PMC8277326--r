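# Independent oracles, deliberately written without reusing package code
# paths beyond plain R.

# Brute-force agglomeration by the Lance-Williams Ward recursion on raw
# dissimilarities (the "ward.D" convention). Returns merge heights and the
# partition after each merge (as canonical sets of leaf indices).
oracle_ward_lw <- function(dm) {
  n <- nrow(dm)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- dm
  heights <- numeric(0)
  partitions <- list()
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    ni <- sizes[i]; nj <- sizes[j]
    newd <- numeric(k)
    for (m in seq_len(k)) {
      if (m == i || m == j) next
      nm <- sizes[m]
      newd[m] <- ((ni + nm) * d[i, m] + (nj + nm) * d[j, m] -
                    nm * d[i, j]) / (ni + nj + nm)
    }
    merged <- sort(c(active[[i]], active[[j]]))
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
    partitions[[length(partitions) + 1L]] <-
      canonical_partition(active)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(sets) {
  sets <- lapply(unname(sets), function(s) as.integer(sort(s)))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}

# Partitions of an hclust tree after each merge, canonicalized the same way.
hclust_partitions <- function(hc, n) {
  lapply((n - 1):1, function(k) {
    labs <- stats::cutree(hc, k)
    canonical_partition(split(seq_len(n), labs))
  })
}

# Full-joint enumeration for a 2-class discrete Bayes net in which every
# predictor is a leaf with parents (class) or (class, phenotype). `cpts` is
# a list of (ncat x 2) matrices or (ncat x 2 x 3) arrays.
oracle_posterior <- function(prior, cpts, cats, evidence,
                             phen_prior = NULL, phenotype = NULL) {
  vars <- names(cpts)
  phen_states <- if (is.null(phen_prior)) NA else seq_along(phen_prior)
  grid <- expand.grid(c(list(osa = 0:1,
                             ph = if (is.null(phen_prior)) 1 else
                               if (is.null(phenotype)) phen_states else
                                 phenotype),
                        lapply(cats, seq_along)),
                      stringsAsFactors = FALSE)
  joint <- vapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    p <- if (g$osa == 1) prior else 1 - prior
    if (!is.null(phen_prior)) p <- p * phen_prior[g$ph]
    for (v in vars) {
      pv <- if (length(dim(cpts[[v]])) == 3L) {
        cpts[[v]][g[[v]], g$osa + 1, g$ph]
      } else {
        cpts[[v]][g[[v]], g$osa + 1]
      }
      p <- p * pv
    }
    p
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) {
    keep <- keep & grid[[v]] == evidence[[v]]
  }
  sum(joint[keep & grid$osa == 1]) / sum(joint[keep])
}

# Normalized Mann-Whitney pairwise count with ties counted half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
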