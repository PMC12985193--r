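# Independent brute-force oracles, kept deliberately naive (double loops,
# full enumeration) so they share no code path with the implementation.

bf_minkowski <- function(u, v, p = 1) {
  s <- 0
  for (i in seq_along(u)) s <- s + abs(u[i] - v[i])^p
  s^(1 / p)
}

bf_nearest_label <- function(x, cohort, label, k = 1, p = 1,
                             exclude_id = NULL) {
  d <- c()
  for (i in seq_along(cohort$case_id)) {
    if (cohort$labels[i] != label) next
    if (!is.null(exclude_id) && cohort$case_id[i] == exclude_id) next
    d <- c(d, bf_minkowski(x, cohort$features[i, ], p))
  }
  mean(sort(d)[seq_len(k)])
}

bf_within_all_pairs <- function(M, p = 1) {
  d <- c()
  for (i in seq_len(nrow(M) - 1L)) {
    for (j in (i + 1L):nrow(M)) {
      d <- c(d, bf_minkowski(M[i, ], M[j, ], p))
    }
  }
  d
}

bf_within_nearest_only <- function(M, p = 1) {
  vapply(seq_len(nrow(M)), function(i) {
    min(vapply(setdiff(seq_len(nrow(M)), i), function(j) {
      bf_minkowski(M[i, ], M[j, ], p)
    }, numeric(1)))
  }, numeric(1))
}

bf_mean_nearest_cross <- function(A, B, p = 1, same = FALSE) {
  mean(vapply(seq_len(nrow(A)), function(i) {
    js <- seq_len(nrow(B))
    if (same) js <- setdiff(js, i)
    min(vapply(js, function(j) bf_minkowski(A[i, ], B[j, ], p), numeric(1)))
  }, numeric(1)))
}

bf_quantiles <- function(d) {
  stats::setNames(stats::quantile(d, c(0, .25, .5, .75, 1), names = FALSE),
                  c("min", "q25", "median", "q75", "max"))
}

# small random labelled cohort for oracle-equivalence checks
random_cohort <- function(n, n_features = 2, seed = 1) {
  withr::with_seed(seed, {
    n_neg <- max(2L, rbinom(1L, n - 4L, 0.5) + 2L)
    n_pos <- n - n_neg
    tbl <- tibble::tibble(
      case_id = sprintf("c%02d", seq_len(n)),
      label = rep(c("LR", "HR"), c(n_neg, n_pos)))
    for (j in seq_len(n_features)) {
      tbl[[paste0("f", j)]] <- rnorm(n, sd = 2)
    }
    labeled_cohort(tbl)
  })
}

# within-group quantile table shaped like a published training-data summary
published_lr_hr_quantiles <- function() {
  q <- cbind(LR = c(0.04, 0.13, 0.20, 0.34, 2.45),
             HR = c(0.02, 0.09, 0.19, 0.38, 2.87))
  rownames(q) <- c("min", "q25", "median", "q75", "max")
  q
}
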