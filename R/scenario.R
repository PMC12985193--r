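#' Synthetic feature-space scenario specification
#'
#' Describes a seeded two-class synthetic cohort emulating the qualitative
#' feature-space regimes that drive distance-based uncertainty:
#' \describe{
#'   \item{`EVEN_COVERAGE`}{both classes spread evenly over the same region,
#'     so within-group median distances are roughly equal — the (unrealistic)
#'     ideal of a densely, uniformly sampled feature space.}
#'   \item{`CLUSTERED_NEG_SPARSE_POS`}{the negative class forms a tight
#'     cluster while the positive class is dispersed, leaving empty space
#'     covered only sparsely by positive examples.}
#'   \item{`TWO_SEPARATED_CLUSTERS`}{two similarly tight clusters far apart,
#'     with empty feature space between them.}
#'   \item{`NONLINEAR_BOUNDARY`}{two interleaved crescents, so that a linear
#'     decision boundary demonstrably fails and distance-based uncertainty
#'     disagrees with it in instructive ways.}
#' }
#' Default class sizes are 85 negative / 47 positive, the scale of a typical
#' small rare-disease imaging cohort, so demo outputs resemble realistic
#' cohort sizes.
#'
#' @param scenario_kind One of the four regimes above.
#' @param n_negative,n_positive Cases per class (each >= 2).
#' @param centers 2-row matrix of per-label cluster centers (rows: negative,
#'   positive); defaults depend on the regime. Ignored by
#'   `NONLINEAR_BOUNDARY`.
#' @param spread Length-2 positive vector of per-label dispersion scales
#'   (noise standard deviation); defaults depend on the regime.
#' @param n_features Feature-space dimensionality (default 2). Crescents are
#'   drawn in the first two dimensions; extra dimensions get pure noise.
#' @param noise Within-cluster noise family: `"gaussian"` (default,
#'   independent per-feature normal) or `"uniform"` (independent per-feature
#'   uniform of matching standard deviation).
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @param seed Integer seed; identical spec + seed reproduce the cohort
#'   exactly.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_kind = c("EVEN_COVERAGE",
                                            "CLUSTERED_NEG_SPARSE_POS",
                                            "TWO_SEPARATED_CLUSTERS",
                                            "NONLINEAR_BOUNDARY"),
                          n_negative = 85L, n_positive = 47L,
                          centers = NULL, spread = NULL, n_features = 2L,
                          noise = c("gaussian", "uniform"),
                          label_names = c(negative = "LR", positive = "HR"),
                          seed = 1L) {
  scenario_kind <- match.arg(scenario_kind)
  noise <- match.arg(noise)
  if (n_negative < 2L || n_positive < 2L) {
    stop("need >= 2 cases per label", call. = FALSE)
  }
  if (n_features < 2L) stop("n_features must be >= 2", call. = FALSE)
  defaults <- scenario_defaults(scenario_kind, n_features)
  if (is.null(centers)) centers <- defaults$centers
  if (is.null(spread)) spread <- defaults$spread
  if (length(spread) == 1L) spread <- rep(spread, 2L)
  if (any(spread <= 0)) stop("spreads must be > 0", call. = FALSE)
  centers <- rbind(centers)
  if (nrow(centers) != 2L || ncol(centers) != n_features) {
    stop("centers must be a 2 x n_features matrix", call. = FALSE)
  }
  structure(list(scenario_kind = scenario_kind,
                 n_negative = as.integer(n_negative),
                 n_positive = as.integer(n_positive),
                 centers = centers, spread = as.numeric(spread),
                 n_features = as.integer(n_features), noise = noise,
                 label_names = normalize_label_names(label_names),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

scenario_defaults <- function(kind, n_features) {
  pad <- function(v) c(v, rep(0, n_features - 2L))
  switch(kind,
    EVEN_COVERAGE = list(centers = rbind(pad(c(0, 0)), pad(c(0, 0))),
                         spread = c(1, 1)),
    CLUSTERED_NEG_SPARSE_POS = list(centers = rbind(pad(c(0, 0)),
                                                    pad(c(2, 2))),
                                    spread = c(0.3, 1.2)),
    TWO_SEPARATED_CLUSTERS = list(centers = rbind(pad(c(0, 0)),
                                                  pad(c(8, 8))),
                                  spread = c(0.5, 0.5)),
    NONLINEAR_BOUNDARY = list(centers = rbind(pad(c(0, 0)), pad(c(1, 0.5))),
                              spread = c(0.15, 0.15)))
}

draw_noise <- function(n, p, scale, family) {
  if (family == "gaussian") {
    matrix(stats::rnorm(n * p, sd = scale), nrow = n)
  } else {
    # uniform of the same standard deviation: half-width = scale * sqrt(3)
    h <- scale * sqrt(3)
    matrix(stats::runif(n * p, -h, h), nrow = n)
  }
}

#' Generate a synthetic labelled cohort from a scenario specification
#'
#' A pure function of (spec, seed): the same specification always yields a
#' byte-identical cohort. `EVEN_COVERAGE` draws both classes from the same
#' distribution around a shared center; the clustered regimes draw each
#' class around its own center at its own spread; `NONLINEAR_BOUNDARY`
#' places the classes on two interleaved crescent arcs plus noise.
#'
#' @param spec A [scenario_spec()].
#' @param scaling Feature scaling fitted on the generated cohort
#'   (passed to [labeled_cohort()]).
#' @return A [labeled_cohort()] with case ids `neg_001, ..., pos_001, ...`
#'   (prefixed by the label names).
#' @export
#' @examples
#' cohort <- generate_cohort(scenario_spec("TWO_SEPARATED_CLUSTERS", seed = 7))
#' cohort
generate_cohort <- function(spec, scaling = "none") {
  stopifnot(inherits(spec, "scenario_spec"))
  ln <- spec$label_names
  X <- withr::with_seed(spec$seed, {
    if (spec$scenario_kind == "NONLINEAR_BOUNDARY") {
      moons <- function(n, inner) {
        t <- stats::runif(n, 0, pi)
        base <- if (!inner) cbind(cos(t), sin(t)) else
          cbind(1 - cos(t), 0.5 - sin(t))
        cbind(base, matrix(0, n, spec$n_features - 2L))
      }
      rbind(moons(spec$n_negative, inner = FALSE) +
              draw_noise(spec$n_negative, spec$n_features, spec$spread[1L],
                         spec$noise),
            moons(spec$n_positive, inner = TRUE) +
              draw_noise(spec$n_positive, spec$n_features, spec$spread[2L],
                         spec$noise))
    } else {
      rbind(sweep(draw_noise(spec$n_negative, spec$n_features,
                             spec$spread[1L], spec$noise),
                  2L, spec$centers[1L, ], "+"),
            sweep(draw_noise(spec$n_positive, spec$n_features,
                             spec$spread[2L], spec$noise),
                  2L, spec$centers[2L, ], "+"))
    }
  })
  colnames(X) <- paste0("f", seq_len(spec$n_features))
  ids <- c(sprintf("%s_%03d", tolower(ln[["negative"]]),
                   seq_len(spec$n_negative)),
           sprintf("%s_%03d", tolower(ln[["positive"]]),
                   seq_len(spec$n_positive)))
  tbl <- tibble::tibble(case_id = ids,
                        label = rep(unname(ln), c(spec$n_negative,
                                                  spec$n_positive)))
  for (j in seq_len(ncol(X))) tbl[[colnames(X)[j]]] <- X[, j]
  tbl <- new_case_table(tbl, feature_names = colnames(X), label_names = ln)
  labeled_cohort(tbl, label_names = ln, scaling = scaling)
}

#' Write a cohort back out as a standard feature table
#'
#' Emits the cohort's original-scale features (any fitted scaling is
#' inverted first) in the CSV schema that [read_feature_table()] consumes
#' (`case_id`, features, `label`).
#'
#' @param cohort A [labeled_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(case_id = cohort$case_id,
                   invert_scaling(cohort$features, cohort$scaling),
                   label = cohort$labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic test cases in chosen feature-space regimes
#'
#' Produces unlabelled test cases positioned relative to a training cohort:
#' \describe{
#'   \item{`IN_CLUSTER`}{small perturbations of randomly chosen training
#'     cases of one label — low uncertainty expected.}
#'   \item{`NEAR_BOUNDARY`}{points equidistant (in the cohort's metric) from
#'     the two label groups, found by bisection along segments joining
#'     random opposite-label training pairs — per-label distances nearly tie.}
#'   \item{`OUTLIER_EMPTY_SPACE`}{points pushed away from the cohort until
#'     farther from every training case than the cohort's maximum
#'     within-group distance — the empty-feature-space regime.}
#' }
#'
#' @param cohort A [labeled_cohort()].
#' @param kind `"IN_CLUSTER"`, `"NEAR_BOUNDARY"` or `"OUTLIER_EMPTY_SPACE"`.
#' @param n Number of cases to generate (> 0).
#' @param seed Integer seed.
#' @param label For `IN_CLUSTER`, which label's cluster to land in
#'   (default: the negative label).
#' @param p Minkowski order for the distance computations used in
#'   construction.
#' @return A `case_table` tibble of `n` unlabelled cases on the cohort's
#'   feature scale.
#' @export
generate_boundary_cases <- function(cohort,
                                    kind = c("IN_CLUSTER", "NEAR_BOUNDARY",
                                             "OUTLIER_EMPTY_SPACE"),
                                    n, seed = 1L, label = NULL, p = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  ln <- cohort$label_names
  if (is.null(label)) label <- ln[["negative"]]
  check_label(cohort, label)
  X <- cohort$features

  pts <- withr::with_seed(seed, {
    switch(kind,
      IN_CLUSTER = {
        M <- group_matrix(cohort, label)
        nn_d <- if (nrow(M) >= 2L) {
          stats::median(within_group_population(cohort, label,
                                                "nearest-only", p))
        } else 1e-3
        idx <- sample.int(nrow(M), n, replace = TRUE)
        M[idx, , drop = FALSE] +
          matrix(stats::rnorm(n * ncol(M), sd = 0.05 * max(nn_d, 1e-12)),
                 nrow = n)
      },
      NEAR_BOUNDARY = {
        A <- group_matrix(cohort, ln[["negative"]])
        B <- group_matrix(cohort, ln[["positive"]])
        t(vapply(seq_len(n), function(i) {
          a <- A[sample.int(nrow(A), 1L), ]
          b <- B[sample.int(nrow(B), 1L), ]
          # d_neg - d_pos is continuous in t and changes sign along the
          # segment; bisection localizes the equidistance point
          f <- function(t) {
            x <- (1 - t) * a + t * b
            min(point_to_rows(x, A, p)) - min(point_to_rows(x, B, p))
          }
          lo <- 0; hi <- 1
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            if (f(mid) <= 0) lo <- mid else hi <- mid
          }
          (1 - lo) * a + lo * b
        }, numeric(ncol(X))))
      },
      OUTLIER_EMPTY_SPACE = {
        maxwg <- max(within_group_population(cohort, ln[["negative"]],
                                             "all-pairs", p),
                     within_group_population(cohort, ln[["positive"]],
                                             "all-pairs", p))
        ctr <- colMeans(X)
        t(vapply(seq_len(n), function(i) {
          dir <- stats::rnorm(ncol(X))
          dir <- dir / sqrt(sum(dir^2))
          r <- maxwg + 1
          x <- ctr + r * dir
          while (min(point_to_rows(x, X, p)) <= maxwg) {
            r <- r * 2
            x <- ctr + r * dir
          }
          x
        }, numeric(ncol(X))))
      })
  })
  colnames(pts) <- cohort$feature_names
  pts <- invert_scaling(pts, cohort$scaling) # back to the input feature scale
  tbl <- tibble::tibble(case_id = sprintf("%s_%03d", tolower(kind),
                                          seq_len(n)))
  for (j in seq_len(ncol(pts))) tbl[[colnames(pts)[j]]] <- pts[, j]
  new_case_table(tbl, feature_names = cohort$feature_names, label_names = ln)
}
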