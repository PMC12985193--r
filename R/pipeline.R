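#' Assemble a run configuration
#'
#' Gathers every tunable of the per-case scoring pipeline into one
#' serializable object, so a run can be reproduced from the resolved
#' configuration written next to its outputs.
#'
#' @param k Nearest-neighbour count for per-label distances.
#' @param p Minkowski order (1 = Manhattan, the default and the setting the
#'   worked examples use).
#' @param uq_variant `"opposite-label"` or `"global-min"` (see
#'   [score_cases()]).
#' @param scaling Feature scaling fitted on the training cohort: `"none"`,
#'   `"minmax"` or `"zscore"`.
#' @param threshold Fixed probability cut-off in (0, 1), or `NULL` to
#'   calibrate to the training event rate.
#' @param quantile_definition Within-group pairwise population for summaries:
#'   `"all-pairs"` or `"nearest-only"`.
#' @param traffic_light A [traffic_light_config()], or `NULL` to omit
#'   traffic-light categorization.
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @param tie_break `"indeterminate"` (default) leaves exact UQ ties as
#'   `INDETERMINATE`; `"predicted"` resolves them to the classifier's
#'   predicted class.
#' @param seed Integer seed for any stochastic step.
#' @return Object of class `run_config`.
#' @export
run_config <- function(k = 1L, p = 1, uq_variant = "opposite-label",
                       scaling = "none", threshold = NULL,
                       quantile_definition = "all-pairs",
                       traffic_light = traffic_light_config(),
                       label_names = c(negative = "LR", positive = "HR"),
                       tie_break = c("indeterminate", "predicted"),
                       seed = 1L) {
  tie_break <- match.arg(tie_break)
  structure(list(k = as.integer(k), p = p, uq_variant = uq_variant,
                 scaling = scaling, threshold = threshold,
                 quantile_definition = quantile_definition,
                 traffic_light = traffic_light,
                 label_names = normalize_label_names(label_names),
                 tie_break = tie_break, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize the resolved run configuration
#'
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$traffic_light)) cfg$traffic_light <- unclass(cfg$traffic_light)
  cfg$label_names <- as.list(cfg$label_names)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`) holding any subset of
#'   the [run_config()] fields; unset fields take the defaults.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  tl <- if (!is.null(raw$traffic_light)) {
    do.call(traffic_light_config, raw$traffic_light)
  } else {
    traffic_light_config()
  }
  args <- raw[intersect(names(raw),
                        c("k", "p", "uq_variant", "scaling", "threshold",
                          "quantile_definition", "label_names", "tie_break",
                          "seed"))]
  if (!is.null(args$label_names)) args$label_names <- unlist(args$label_names)
  do.call(run_config, c(args, list(traffic_light = tl)))
}

as_cohort <- function(x, config) {
  if (inherits(x, "labeled_cohort")) return(x)
  tbl <- if (is.character(x)) {
    read_feature_table(x, id_col = "case_id", label_col = "label",
                       label_names = config$label_names)
  } else x
  labeled_cohort(tbl, label_names = config$label_names,
                 scaling = config$scaling)
}

as_case_table <- function(x, config) {
  if (is.character(x)) {
    header <- names(utils::read.csv(x, nrows = 1L, check.names = FALSE))
    read_feature_table(x, id_col = "case_id",
                       label_col = if ("label" %in% header) "label",
                       prob_col = if ("prob_positive" %in% header)
                         "prob_positive",
                       label_names = config$label_names)
  } else x
}

#' Summarize training-cohort distances to files
#'
#' Computes the training cohort's [distance_summary()] under the configured
#' pairwise definition and metric and writes it as CSV and JSON.
#'
#' @param train A [labeled_cohort()], labelled `case_table`, or path to a
#'   labelled feature CSV.
#' @param out_prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param config A [run_config()].
#' @return The `distance_summary`, invisibly.
#' @export
run_summarize <- function(train, out_prefix, config = run_config()) {
  cohort <- as_cohort(train, config)
  s <- distance_summary(cohort, definition = config$quantile_definition,
                        p = config$p)
  write_distance_summary(s, csv = paste0(out_prefix, ".csv"),
                         json = paste0(out_prefix, ".json"))
  invisible(s)
}

#' Score test cases end to end
#'
#' The full per-case pipeline: fit (or accept) positive-class probabilities,
#' predict the class at the decision threshold, measure per-label
#' nearest-neighbour distances against the training cohort, score both
#' candidate labels, select the final class by minimum uncertainty, and
#' attach the traffic-light category. Every input case yields exactly one
#' report row; disagreements between the classifier's prediction and the
#' distance-based final class, and infinite scores, are raised as warnings —
#' these are the "difficult cases" the method exists to surface.
#'
#' @param train Training input: a [labeled_cohort()], labelled `case_table`,
#'   or CSV path.
#' @param test Test input: `case_table`, data frame with feature columns
#'   (optionally `prob_positive`), or CSV path.
#' @param config A [run_config()].
#' @param out Optional output path for the report file (written with
#'   [write_reports()]).
#' @param format Report file format when `out` is given.
#' @return Tibble of case reports (one row per test case) with columns
#'   `case_id, predicted_class, probability_positive,
#'   distance_to_nearest_negative, distance_to_nearest_positive,
#'   uq_negative, uq_positive, final_class, traffic_light`.
#' @export
run_score <- function(train, test, config = run_config(), out = NULL,
                      format = c("csv", "jsonl")) {
  format <- match.arg(format)
  cohort <- as_cohort(train, config)
  test_tbl <- as_case_table(test, config)
  ln <- cohort$label_names

  missing_f <- setdiff(cohort$feature_names,
                       attr(test_tbl, "feature_names") %||% names(test_tbl))
  if (length(missing_f) > 0L) {
    stop("schema error: test table lacks training feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }

  dc <- if (is.null(config$threshold)) {
    calibrate_threshold(cohort$labels, positive_label = ln[["positive"]])
  } else {
    decision_config(config$threshold, positive_label = ln[["positive"]])
  }
  prob <- if ("prob_positive" %in% names(test_tbl)) {
    test_tbl$prob_positive
  } else {
    fit_reference_classifier(cohort)(test_tbl)
  }
  predicted <- predict_class(prob, dc, negative_label = ln[["negative"]])

  nd <- neighbor_distances(test_tbl, cohort, k = config$k, p = config$p)
  uq <- score_cases(nd, variant = config$uq_variant, label_names = ln)
  final <- uq$final_class
  if (config$tie_break == "predicted") {
    final[final == "INDETERMINATE"] <- predicted[final == "INDETERMINATE"]
  }

  tl <- rep(NA_character_, nrow(nd))
  if (!is.null(config$traffic_light)) {
    s <- distance_summary(cohort, definition = config$quantile_definition,
                          p = config$p)
    d_pred <- ifelse(predicted == ln[["negative"]], nd$d_negative,
                     nd$d_positive)
    tl <- vapply(seq_along(d_pred), function(i) {
      categorize_uncertainty(d_pred[i], s, predicted[i],
                             config$traffic_light)
    }, character(1L))
  }

  reports <- tibble::tibble(
    case_id = nd$case_id,
    predicted_class = predicted,
    probability_positive = prob,
    distance_to_nearest_negative = nd$d_negative,
    distance_to_nearest_positive = nd$d_positive,
    uq_negative = uq$uq_negative,
    uq_positive = uq$uq_positive,
    final_class = final,
    traffic_light = tl)

  disagree <- final != "INDETERMINATE" & final != predicted
  if (any(disagree)) {
    warning("classifier prediction and distance-based final class disagree ",
            "for case(s): ",
            paste(reports$case_id[disagree], collapse = ", "),
            call. = FALSE)
  }
  if (any(is.infinite(uq$uq_negative) | is.infinite(uq$uq_positive))) {
    warning("infinite uncertainty score(s): case coincides with an ",
            "opposite-label training example", call. = FALSE)
  }
  if (!is.null(out)) {
    write_reports(reports, out, format = format)
    write_run_config(config, paste0(out, ".config.json"))
  }
  reports
}
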