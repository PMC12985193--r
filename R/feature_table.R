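#' Read a tabular case feature file
#'
#' Reads a CSV (or TSV) table of cases, one row per case, with an identifier
#' column, numeric feature columns, and an optional binary risk-label column.
#' The table is validated strictly: missing declared columns, duplicated case
#' identifiers, and non-numeric or missing feature cells are errors, never
#' silently repaired — the distance-based uncertainty score has no defined
#' behaviour for missing features, so imputation is deliberately refused.
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param id_col Name of the case-identifier column.
#' @param label_col Name of the binary label column, or `NULL` when the table
#'   is unlabelled (e.g. test cases).
#' @param feature_cols Character vector of feature column names. When `NULL`,
#'   every column other than `id_col`, `label_col` and `prob_col` is taken as
#'   a feature.
#' @param prob_col Optional name of a column holding precomputed
#'   positive-class probabilities in \[0, 1\].
#' @param label_names Named character vector `c(negative = ..., positive = ...)`
#'   giving the two permitted label values; defaults to `c("LR", "HR")`
#'   (low-/high-risk).
#' @param sep Field separator; `","` (default) or `"\t"` for TSV.
#'
#' @return A tibble of class `case_table` with columns `case_id`, optionally
#'   `label` and `prob_positive`, and one numeric column per feature. The
#'   feature names and label names are carried in attributes
#'   `feature_names` / `label_names`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("id,sphericity,p90,label",
#'              "a,0.80,110,LR", "b,0.55,190,HR", "c,0.71,150,LR"), path)
#' read_feature_table(path, id_col = "id", label_col = "label")
read_feature_table <- function(path, id_col = "case_id", label_col = NULL,
                               feature_cols = NULL, prob_col = NULL,
                               label_names = c(negative = "LR", positive = "HR"),
                               sep = ",") {
  if (!file.exists(path)) {
    stop("feature table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  declared <- c(id_col, label_col, prob_col, feature_cols)
  missing_cols <- setdiff(declared, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(raw), c(id_col, label_col, prob_col))
  }
  if (length(feature_cols) == 0L) {
    stop("schema error: no feature columns in ", path, call. = FALSE)
  }

  case_id <- raw[[id_col]]
  if (anyDuplicated(case_id)) {
    dup <- unique(case_id[duplicated(case_id)])
    stop("validation error: duplicated case_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  feats <- lapply(feature_cols, function(col) {
    suppressWarnings(as.numeric(raw[[col]]))
  })
  names(feats) <- feature_cols
  bad <- unique(unlist(lapply(feats, function(v) {
    case_id[is.na(v) | !is.finite(v)]
  })))
  if (length(bad) > 0L) {
    stop("validation error: non-numeric, missing or non-finite feature ",
         "value(s) for case(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  out <- tibble::tibble(case_id = as.character(case_id))
  if (!is.null(label_col)) {
    lab <- raw[[label_col]]
    unknown <- setdiff(unique(lab), unname(label_names))
    if (length(unknown) > 0L) {
      stop("validation error: unknown label value(s): ",
           paste(unknown, collapse = ", "), "; expected ",
           paste(label_names, collapse = "/"), call. = FALSE)
    }
    out$label <- lab
  }
  if (!is.null(prob_col)) {
    p <- suppressWarnings(as.numeric(raw[[prob_col]]))
    if (any(is.na(p) | p < 0 | p > 1)) {
      stop("validation error: probabilities must lie in [0, 1]", call. = FALSE)
    }
    out$prob_positive <- p
  }
  for (col in feature_cols) out[[col]] <- feats[[col]]

  new_case_table(out, feature_names = feature_cols, label_names = label_names)
}

new_case_table <- function(tbl, feature_names, label_names) {
  structure(tbl,
            feature_names = feature_names,
            label_names = normalize_label_names(label_names),
            class = c("case_table", class(tbl)))
}

normalize_label_names <- function(label_names) {
  stopifnot(length(label_names) == 2L)
  if (is.null(names(label_names)) || !setequal(names(label_names),
                                               c("negative", "positive"))) {
    names(label_names) <- c("negative", "positive")
  }
  if (label_names[["negative"]] == label_names[["positive"]]) {
    stop("label names must be distinct", call. = FALSE)
  }
  label_names[c("negative", "positive")]
}

#' Extract the feature matrix of a case table or cohort
#'
#' @param x A `case_table` or `labeled_cohort`.
#' @return Numeric matrix, one row per case (rownames = case ids).
#' @export
case_features <- function(x) {
  if (inherits(x, "labeled_cohort")) return(x$features)
  fn <- attr(x, "feature_names")
  m <- as.matrix(as.data.frame(x)[, fn, drop = FALSE])
  rownames(m) <- x$case_id
  m
}

#' Construct a labelled training cohort
#'
#' Bundles a labelled case table into the reference set that all distances
#' are measured against, optionally fitting a feature scaling on it. Scaling
#' parameters are always fitted on this cohort only and are re-applied to any
#' test case scored against it.
#'
#' @param table A `case_table` (see [read_feature_table()]) with a `label`
#'   column, or a data frame with `case_id`, `label` and numeric feature
#'   columns.
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @param scaling One of `"none"` (default), `"minmax"` (per-feature min–max
#'   to \[0, 1\]) or `"zscore"` (per-feature centring/scaling). The paper's
#'   metric is scale-dependent, so the choice is recorded on the cohort and
#'   echoed in every report.
#'
#' @return An object of class `labeled_cohort`: list with elements
#'   `case_id`, `features` (scaled numeric matrix), `labels`, `label_names`,
#'   `feature_names` and `scaling` (method + fitted parameters).
#' @export
labeled_cohort <- function(table,
                           label_names = attr(table, "label_names") %||%
                             c(negative = "LR", positive = "HR"),
                           scaling = c("none", "minmax", "zscore")) {
  scaling <- match.arg(scaling)
  label_names <- normalize_label_names(label_names)
  if (!"label" %in% names(table)) {
    stop("a labelled cohort requires a 'label' column", call. = FALSE)
  }
  fn <- attr(table, "feature_names") %||%
    setdiff(names(table), c("case_id", "label", "prob_positive"))
  X <- as.matrix(as.data.frame(table)[, fn, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- table$case_id
  labels <- as.character(table$label)
  if (!all(labels %in% label_names)) {
    stop("labels must all be one of ", paste(label_names, collapse = "/"),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = label_names))
  if (any(counts < 1L)) {
    stop("cohort must contain at least one case of each label; missing: ",
         paste(label_names[counts < 1L], collapse = ", "), call. = FALSE)
  }

  sc <- fit_scaling(X, scaling)
  structure(list(case_id = as.character(table$case_id),
                 features = apply_scaling(X, sc),
                 labels = labels,
                 label_names = label_names,
                 feature_names = fn,
                 scaling = sc),
            class = "labeled_cohort")
}

fit_scaling <- function(X, method) {
  switch(method,
    none = list(method = "none"),
    minmax = {
      lo <- apply(X, 2L, min)
      hi <- apply(X, 2L, max)
      rng <- hi - lo
      rng[rng == 0] <- 1 # constant feature maps to 0, not NaN
      list(method = "minmax", lo = lo, range = rng)
    },
    zscore = {
      mu <- colMeans(X)
      sd <- apply(X, 2L, stats::sd)
      sd[sd == 0] <- 1
      list(method = "zscore", center = mu, scale = sd)
    })
}

apply_scaling <- function(X, sc) {
  switch(sc$method,
    none = X,
    minmax = sweep(sweep(X, 2L, sc$lo, "-"), 2L, sc$range, "/"),
    zscore = sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/"))
}

invert_scaling <- function(X, sc) {
  switch(sc$method,
    none = X,
    minmax = sweep(sweep(X, 2L, sc$range, "*"), 2L, sc$lo, "+"),
    zscore = sweep(sweep(X, 2L, sc$scale, "*"), 2L, sc$center, "+"))
}

#' @export
print.labeled_cohort <- function(x, ...) {
  counts <- table(factor(x$labels, levels = x$label_names))
  cat("<labeled_cohort> ", length(x$case_id), " cases (",
      x$label_names[["negative"]], ": ", counts[[1L]], ", ",
      x$label_names[["positive"]], ": ", counts[[2L]], "), ",
      length(x$feature_names), " feature(s), scaling = ",
      x$scaling$method, "\n", sep = "")
  invisible(x)
}

# Scale test-case features with the parameters fitted on the training cohort.
scale_like_cohort <- function(cohort, X) {
  apply_scaling(X[, cohort$feature_names, drop = FALSE], cohort$scaling)
}

report_columns <- c("case_id", "predicted_class", "probability_positive",
                    "distance_to_nearest_negative",
                    "distance_to_nearest_positive",
                    "uq_negative", "uq_positive", "final_class",
                    "traffic_light")

#' Write per-case uncertainty reports
#'
#' Serializes case reports (the per-case output of [run_score()]) to CSV or
#' JSON-lines with a fixed, documented column order:
#' `case_id, predicted_class, probability_positive,
#' distance_to_nearest_negative, distance_to_nearest_positive, uq_negative,
#' uq_positive, final_class, traffic_light`.
#' Numeric fields are rendered at `digits` decimals (default 2, the rendering
#' used in clinical report tables); an infinite uncertainty score — a case
#' coinciding with an opposite-label training example — is written as the
#' literal token `"inf"`.
#'
#' @param reports Data frame of case reports (non-empty).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param digits Decimal places for numeric fields.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, format = c("csv", "jsonl"),
                          digits = 2L) {
  format <- match.arg(format)
  if (NROW(reports) == 0L) stop("no reports to write", call. = FALSE)
  cols <- intersect(report_columns, names(reports))
  df <- as.data.frame(reports)[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1L))
  rendered <- df
  for (col in names(df)[num]) {
    v <- df[[col]]
    out <- ifelse(is.infinite(v), "inf", formatC(v, digits = digits,
                                                 format = "f"))
    rendered[[col]] <- out
  }
  if (format == "csv") {
    utils::write.csv(rendered, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(rendered))) {
      row <- as.list(rendered[i, , drop = FALSE])
      for (col in names(df)[num]) {
        row[[col]] <- if (identical(row[[col]], "inf")) "inf" else
          as.numeric(row[[col]])
      }
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
    }
  }
  invisible(path)
}

#' Read back a report file written by [write_reports()]
#'
#' @param path Report file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return Tibble with the report columns; the `"inf"` sentinel is restored
#'   to `Inf`.
#' @export
read_reports <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  numeric_cols <- c("probability_positive", "distance_to_nearest_negative",
                    "distance_to_nearest_positive", "uq_negative",
                    "uq_positive")
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  } else {
    rows <- lapply(readLines(path, encoding = "UTF-8"), function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, lapply(rows, function(r) {
      r[] <- lapply(r, as.character)
      r
    }))
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- df[[col]]
    df[[col]] <- ifelse(v == "inf", Inf, suppressWarnings(as.numeric(v)))
  }
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
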