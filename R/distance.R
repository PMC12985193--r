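#' Manhattan (L1) distance between two feature vectors
#'
#' The sum of absolute per-coordinate differences. This is the default metric
#' throughout the package: it is the simplest metric that makes
#' "distance to familiar territory" in feature space concrete, and per-label
#' nearest-neighbour versions of it drive the uncertainty score.
#'
#' @param u,v Numeric vectors over the same ordered feature set. Named
#'   vectors must agree in names and order.
#' @return Nonnegative scalar distance.
#' @seealso [minkowski_distance()] for the p-norm generalization.
#' @export
#' @examples
#' manhattan_distance(c(0, 0), c(1, 2)) # 3
manhattan_distance <- function(u, v) {
  minkowski_distance(u, v, p = 1)
}

#' Minkowski distance between two feature vectors
#'
#' `(sum |u_i - v_i|^p)^(1/p)` for `p >= 1`. `p = 1` is the Manhattan
#' distance, the only setting used in the headline method; larger `p` is
#' provided for sensitivity analyses.
#'
#' @inheritParams manhattan_distance
#' @param p Minkowski order, `p >= 1`.
#' @return Nonnegative scalar distance.
#' @export
minkowski_distance <- function(u, v, p = 1) {
  if (length(u) != length(v)) {
    stop("feature vectors differ in length (", length(u), " vs ",
         length(v), ")", call. = FALSE)
  }
  if (!is.null(names(u)) && !is.null(names(v)) &&
      !identical(names(u), names(v))) {
    stop("feature vectors have mismatched feature names", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    stop("p must be a single number >= 1", call. = FALSE)
  }
  if (is.infinite(p)) return(max(abs(u - v)))
  sum(abs(u - v)^p)^(1 / p)
}

# Distances from one point to every row of a matrix (Minkowski order p).
point_to_rows <- function(x, M, p = 1) {
  d <- abs(sweep(M, 2L, x, "-"))
  if (is.infinite(p)) return(apply(d, 1L, max))
  rowSums(d^p)^(1 / p)
}

check_label <- function(cohort, label) {
  if (!label %in% cohort$label_names) {
    stop("unknown label '", label, "'; cohort labels are ",
         paste(cohort$label_names, collapse = "/"), call. = FALSE)
  }
  label
}

#' Distance to the nearest (or mean of k nearest) training cases of a label
#'
#' For `k = 1`, the minimum distance from `x` to any training case carrying
#' `label`; for `k > 1`, the arithmetic mean of the `k` smallest such
#' distances — a smoothing that guards the score against single outlying
#' training examples. A distance of exactly 0 means the training set contains
#' a case with identical features.
#'
#' @param x Numeric feature vector (on the same scale as the cohort; apply
#'   the cohort's scaling first if any) or a 1-row feature matrix.
#' @param cohort A [labeled_cohort()].
#' @param label Which label's training cases to measure against.
#' @param k Number of nearest neighbours to average (default 1).
#' @param p Minkowski order (default 1, Manhattan).
#' @param exclude_id Optional case id to exclude (self-pairing, when `x` is
#'   itself a cohort member).
#' @return Nonnegative scalar distance.
#' @export
nearest_label_distance <- function(x, cohort, label, k = 1L, p = 1,
                                   exclude_id = NULL) {
  check_label(cohort, label)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  keep <- cohort$labels == label
  if (!is.null(exclude_id)) keep <- keep & cohort$case_id != exclude_id
  M <- cohort$features[keep, , drop = FALSE]
  if (nrow(M) < k) {
    stop("cohort has only ", nrow(M), " usable case(s) with label '", label,
         "' but k = ", k, call. = FALSE)
  }
  d <- sort(point_to_rows(as.numeric(x), M, p))
  mean(d[seq_len(k)])
}

#' Per-label nearest-neighbour distances for a batch of cases
#'
#' Computes, for every case, its distance to the nearest (mean of `k`
#' nearest) negative-label and positive-label training examples — the two
#' inputs of the uncertainty score. Cases that are themselves cohort members
#' (matched by id) have self-pairing excluded.
#'
#' @param cases A `case_table`, data frame with feature columns, or numeric
#'   feature matrix. Features are rescaled with the cohort's fitted scaling.
#' @inheritParams nearest_label_distance
#' @return Tibble of class `neighbor_distances`: `case_id`, `d_negative`,
#'   `d_positive`, `k`.
#' @export
neighbor_distances <- function(cases, cohort, k = 1L, p = 1) {
  if (is.matrix(cases)) {
    X <- cases
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  } else {
    fn <- attr(cases, "feature_names") %||% cohort$feature_names
    missing_f <- setdiff(cohort$feature_names, fn)
    if (length(missing_f) > 0L) {
      stop("schema error: test cases lack feature(s): ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    }
    X <- as.matrix(as.data.frame(cases)[, cohort$feature_names, drop = FALSE])
    ids <- if ("case_id" %in% names(cases)) as.character(cases$case_id) else
      as.character(seq_len(nrow(X)))
  }
  X <- scale_like_cohort(cohort, X)
  neg <- cohort$label_names[["negative"]]
  pos <- cohort$label_names[["positive"]]
  dn <- dp <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    ex <- if (ids[i] %in% cohort$case_id) ids[i] else NULL
    dn[i] <- nearest_label_distance(X[i, ], cohort, neg, k = k, p = p,
                                    exclude_id = ex)
    dp[i] <- nearest_label_distance(X[i, ], cohort, pos, k = k, p = p,
                                    exclude_id = ex)
  }
  structure(tibble::tibble(case_id = ids, d_negative = dn, d_positive = dp,
                           k = as.integer(k)),
            class = c("neighbor_distances", class(tibble::tibble())))
}

group_matrix <- function(cohort, label) {
  cohort$features[cohort$labels == label, , drop = FALSE]
}

# The two pairwise-distance populations a within-group summary can describe.
within_group_population <- function(cohort, label, definition, p = 1) {
  M <- group_matrix(cohort, check_label(cohort, label))
  if (nrow(M) < 2L) {
    stop("within-group distances need >= 2 cases with label '", label, "'",
         call. = FALSE)
  }
  if (definition == "all-pairs") {
    as.numeric(stats::dist(M, method = "minkowski", p = p))
  } else {
    vapply(seq_len(nrow(M)), function(i) {
      min(point_to_rows(M[i, ], M[-i, , drop = FALSE], p))
    }, numeric(1L))
  }
}

#' Within-group distance quantiles for one label
#'
#' Five-number summary (min, 25%, median, 75%, max) of a label's within-group
#' distance population. Two populations are supported and the choice is an
#' explicit argument, never a hidden default: `"all-pairs"` takes every
#' unordered within-label pair once; `"nearest-only"` takes each member's
#' distance to its nearest same-label neighbour (self excluded). Published
#' summaries rarely state which was used, and the two can differ greatly.
#'
#' @inheritParams nearest_label_distance
#' @param definition `"all-pairs"` or `"nearest-only"`.
#' @return Named numeric vector `c(min, q25, median, q75, max)`.
#' @export
within_group_quantiles <- function(cohort, label,
                                   definition = c("all-pairs", "nearest-only"),
                                   p = 1) {
  definition <- match.arg(definition)
  d <- within_group_population(cohort, label, definition, p)
  q <- stats::quantile(d, probs = c(0, .25, .5, .75, 1), names = FALSE,
                       type = 7)
  stats::setNames(q, c("min", "q25", "median", "q75", "max"))
}

#' Directed mean nearest distance between label groups
#'
#' Mean, over all cases of `from_label`, of each case's minimum distance to a
#' `to_label` case (self excluded when the labels coincide). The directed
#' means are genuinely asymmetric: a tight cluster sitting near one member of
#' a dispersed group yields a small mean in one direction and a large one in
#' the other — the signature of empty feature-space regions between groups.
#'
#' @inheritParams nearest_label_distance
#' @param from_label,to_label Group labels (source and target of the
#'   directed nearest-neighbour search).
#' @return Nonnegative scalar.
#' @export
mean_nearest_cross_distance <- function(cohort, from_label, to_label, p = 1) {
  check_label(cohort, from_label)
  check_label(cohort, to_label)
  A <- group_matrix(cohort, from_label)
  B <- group_matrix(cohort, to_label)
  same <- from_label == to_label
  if (nrow(B) < 1L || (same && nrow(A) < 2L)) {
    stop("not enough cases with label '", to_label,
         "' to measure nearest distances against", call. = FALSE)
  }
  mean(vapply(seq_len(nrow(A)), function(i) {
    targets <- if (same) B[-i, , drop = FALSE] else B
    min(point_to_rows(A[i, ], targets, p))
  }, numeric(1L)))
}

#' Training-cohort distance summary
#'
#' The distance context a clinician needs to interpret an individual case's
#' uncertainty: per-label within-group distance quantiles plus the four
#' directed mean nearest distances (neg→neg, neg→pos, pos→neg, pos→pos).
#' The raw within-group populations are retained so that traffic-light
#' percentiles other than the printed five can be computed later.
#'
#' @inheritParams within_group_quantiles
#' @return Object of class `distance_summary`: list with `quantiles`
#'   (5 × 2 matrix, columns = labels), `mean_nearest` (2 × 2 directed matrix,
#'   rows = from, cols = to), `populations` (per-label distance vectors),
#'   `definition`, `p`, `label_names`, `scaling`.
#' @export
distance_summary <- function(cohort,
                             definition = c("all-pairs", "nearest-only"),
                             p = 1) {
  definition <- match.arg(definition)
  ln <- cohort$label_names
  pops <- lapply(stats::setNames(unname(ln), unname(ln)), function(l) {
    within_group_population(cohort, l, definition, p)
  })
  q <- vapply(pops, function(d) {
    stats::quantile(d, probs = c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  }, numeric(5L))
  rownames(q) <- c("min", "q25", "median", "q75", "max")
  mn <- outer(unname(ln), unname(ln),
              Vectorize(function(a, b) mean_nearest_cross_distance(cohort, a, b, p)))
  dimnames(mn) <- list(from = unname(ln), to = unname(ln))
  structure(list(quantiles = q, mean_nearest = mn, populations = pops,
                 definition = definition, p = p, label_names = ln,
                 scaling = cohort$scaling$method),
            class = "distance_summary")
}

#' Build a distance summary from published quantiles
#'
#' Constructs a `distance_summary` directly from a printed five-number
#' summary table (e.g. transcribed from a publication), without access to the
#' underlying cohort. Only the quantiles present can back traffic-light
#' thresholds; off-grid percentiles raise an error.
#'
#' @param quantiles 5 × 2 numeric matrix; rows `min, q25, median, q75, max`,
#'   one column per label.
#' @param mean_nearest Optional 2 × 2 directed mean nearest-distance matrix.
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @param definition Which pairwise population the quantiles describe, if
#'   known.
#' @return A `distance_summary` without raw populations.
#' @export
#' @examples
#' q <- cbind(LR = c(0.04, 0.13, 0.20, 0.34, 2.45),
#'            HR = c(0.02, 0.09, 0.19, 0.38, 2.87))
#' rownames(q) <- c("min", "q25", "median", "q75", "max")
#' distance_summary_from_quantiles(q)
distance_summary_from_quantiles <- function(quantiles, mean_nearest = NULL,
                                            label_names = c(negative = "LR",
                                                            positive = "HR"),
                                            definition = "unknown") {
  label_names <- normalize_label_names(label_names)
  stopifnot(is.matrix(quantiles), nrow(quantiles) == 5L,
            ncol(quantiles) == 2L)
  rownames(quantiles) <- c("min", "q25", "median", "q75", "max")
  if (is.null(colnames(quantiles))) colnames(quantiles) <- unname(label_names)
  bad <- apply(quantiles, 2L, is.unsorted)
  if (any(bad)) {
    stop("quantiles must be nondecreasing within each label", call. = FALSE)
  }
  structure(list(quantiles = quantiles, mean_nearest = mean_nearest,
                 populations = NULL, definition = definition, p = 1,
                 label_names = label_names, scaling = "unknown"),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> definition =", x$definition,
      "| Minkowski p =", x$p, "\n")
  cat("Within-group distance quantiles:\n")
  print(round(x$quantiles, 4))
  if (!is.null(x$mean_nearest)) {
    cat("Directed mean nearest distances (row -> column):\n")
    print(round(x$mean_nearest, 4))
  }
  invisible(x)
}

#' Export a distance summary as CSV and/or JSON
#'
#' The CSV has one row per statistic (min/25%/50%/75%/max and the four
#' directed means) and one column per label, mirroring the summary-table
#' shape used in clinical reports.
#'
#' @param summary A `distance_summary`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of paths written.
#' @export
write_distance_summary <- function(summary, csv = NULL, json = NULL) {
  ln <- summary$label_names
  if (!is.null(csv)) {
    q <- summary$quantiles
    rows <- data.frame(statistic = c("min", "25%", "50%", "75%", "max"),
                       q, check.names = FALSE, row.names = NULL)
    if (!is.null(summary$mean_nearest)) {
      mn <- summary$mean_nearest
      lab <- unname(ln)
      extra <- data.frame(
        statistic = c(paste0("mean_nearest_", lab[1], "_to_", lab[1]),
                      paste0("mean_nearest_", lab[1], "_to_", lab[2]),
                      paste0("mean_nearest_", lab[2], "_to_", lab[1]),
                      paste0("mean_nearest_", lab[2], "_to_", lab[2])),
        m1 = c(mn[1, 1], NA, mn[2, 1], NA),
        m2 = c(NA, mn[1, 2], NA, mn[2, 2]),
        check.names = FALSE)
      names(extra)[2:3] <- colnames(q)
      rows <- rbind(rows, extra)
    }
    utils::write.csv(rows, csv, row.names = FALSE, na = "")
  }
  if (!is.null(json)) {
    payload <- list(definition = summary$definition, p = summary$p,
                    scaling = summary$scaling,
                    label_names = as.list(ln),
                    quantiles = apply(summary$quantiles, 2L, as.list),
                    mean_nearest = if (!is.null(summary$mean_nearest))
                      apply(summary$mean_nearest, 1L, as.list))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(csv = csv, json = json))
}
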