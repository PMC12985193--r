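#' Traffic-light configuration
#'
#' Percentile thresholds mapping a case's distance to its predicted class
#' onto GREEN/AMBER/RED relative to the training cohort's within-group
#' distance distribution. There are deliberately no hidden defaults beyond
#' the documented (50, 75) illustration: generic uncertainty thresholds are
#' discouraged — every model and clinic should calibrate its own, weighing
#' disease-specific guidelines and the cost of misdiagnosis — so the
#' configuration object is a mandatory argument of [categorize_uncertainty()].
#'
#' @param green_upper_percentile Upper percentile of the GREEN band
#'   (default 50: at or below the within-group median).
#' @param amber_upper_percentile Upper percentile of the AMBER band
#'   (default 75).
#' @param reference Which quantity the percentiles refer to;
#'   `"within-group-distance"` (default) compares the case's distance to the
#'   nearest predicted-label training example against the predicted class's
#'   within-group distance distribution.
#' @return Object of class `traffic_light_config`.
#' @export
traffic_light_config <- function(green_upper_percentile = 50,
                                 amber_upper_percentile = 75,
                                 reference = "within-group-distance") {
  g <- green_upper_percentile
  a <- amber_upper_percentile
  if (!(is.numeric(g) && is.numeric(a) && length(g) == 1L &&
        length(a) == 1L && g > 0 && a < 100 && g < a)) {
    stop("percentiles must satisfy 0 < green_upper < amber_upper < 100",
         call. = FALSE)
  }
  structure(list(green_upper_percentile = g, amber_upper_percentile = a,
                 reference = reference),
            class = "traffic_light_config")
}

# Percentile value of a label's within-group distance population. Raw
# populations back any percentile (linear interpolation between order
# statistics, stats::quantile type 7); quantile-only summaries (published
# tables) can only serve the five printed percentiles.
summary_percentile <- function(summary, label, pct) {
  if (!label %in% colnames(summary$quantiles)) {
    stop("summary has no quantiles for label '", label, "'", call. = FALSE)
  }
  if (!is.null(summary$populations) && label %in% names(summary$populations)) {
    return(stats::quantile(summary$populations[[label]], probs = pct / 100,
                           names = FALSE, type = 7))
  }
  grid <- c(min = 0, q25 = 25, median = 50, q75 = 75, max = 100)
  hit <- names(grid)[grid == pct]
  if (length(hit) == 0L) {
    stop("percentile ", pct, " unavailable: summary stores only quantiles ",
         "at 0/25/50/75/100 and no raw distance population", call. = FALSE)
  }
  summary$quantiles[hit, label]
}

#' Categorize a case's uncertainty as GREEN, AMBER or RED
#'
#' Compares the case's distance to the nearest training example of its
#' predicted class against that class's within-group training distance
#' distribution: at or below the `green_upper_percentile` value is GREEN
#' (uncertainty low), above it but at or below the `amber_upper_percentile`
#' value is AMBER (uncertainty medium — exercise caution), above that is RED
#' (uncertainty high). Bands are half-open with inclusive upper boundaries.
#'
#' @param distance_to_predicted_label Nonnegative distance from the case to
#'   the nearest training example of `predicted_label` (same metric and
#'   feature scaling as the summary).
#' @param summary A [distance_summary()] (or
#'   [distance_summary_from_quantiles()]) of the training cohort.
#' @param predicted_label The case's predicted class.
#' @param config A [traffic_light_config()]; mandatory, no default
#'   thresholds are assumed.
#' @return `"GREEN"`, `"AMBER"` or `"RED"` (vectorized over distances).
#' @export
#' @examples
#' q <- cbind(LR = c(0.04, 0.13, 0.20, 0.34, 2.45),
#'            HR = c(0.02, 0.09, 0.19, 0.38, 2.87))
#' rownames(q) <- c("min", "q25", "median", "q75", "max")
#' s <- distance_summary_from_quantiles(q)
#' categorize_uncertainty(0.21, s, "LR", traffic_light_config()) # AMBER
categorize_uncertainty <- function(distance_to_predicted_label, summary,
                                   predicted_label, config) {
  if (!inherits(config, "traffic_light_config")) {
    stop("config must be a traffic_light_config()", call. = FALSE)
  }
  d <- distance_to_predicted_label
  if (any(d < 0)) stop("distance must be nonnegative", call. = FALSE)
  g <- summary_percentile(summary, predicted_label,
                          config$green_upper_percentile)
  a <- summary_percentile(summary, predicted_label,
                          config$amber_upper_percentile)
  ifelse(d <= g, "GREEN", ifelse(d <= a, "AMBER", "RED"))
}

traffic_light_phrase <- c(
  GREEN = "uncertainty low",
  AMBER = "uncertainty medium - exercise caution",
  RED = "uncertainty high")

#' Render a two-step clinical report for one case
#'
#' Step 1 states the model's predicted class with its positive-class
#' probability; step 2 states the per-label distances, uncertainty scores,
#' the final (argmin-uncertainty) class and the traffic-light category with
#' its standard phrase. Disagreement between the classifier's prediction and
#' the distance-based final class, and indeterminate ties, are flagged
#' explicitly rather than reconciled.
#'
#' @param report One report row: a 1-row data frame (as produced by
#'   [run_score()]) or a named list with the report fields.
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @return Character scalar, the rendered multi-line report.
#' @export
render_two_step_report <- function(report,
                                   label_names = c(negative = "LR",
                                                   positive = "HR")) {
  r <- as.list(as.data.frame(report, stringsAsFactors = FALSE)[1L, ])
  label_names <- normalize_label_names(label_names)
  neg <- label_names[["negative"]]
  pos <- label_names[["positive"]]
  fmt <- function(x) {
    if (is.infinite(x)) "inf" else formatC(x, digits = 2, format = "f")
  }
  lines <- c(
    sprintf("Case %s", r$case_id),
    sprintf("Step 1 - Prediction: class %s (probability of %s class: %s%%)",
            r$predicted_class, pos,
            formatC(100 * r$probability_positive, digits = 0, format = "f")),
    sprintf("Step 2 - Uncertainty:"),
    sprintf("  Distance to nearest %s: %s | nearest %s: %s",
            neg, fmt(r$distance_to_nearest_negative),
            pos, fmt(r$distance_to_nearest_positive)),
    sprintf("  UQ score %s: %s | %s: %s",
            neg, fmt(r$uq_negative), pos, fmt(r$uq_positive)),
    if (identical(r$final_class, "INDETERMINATE")) {
      "  Final risk class: INDETERMINATE (the two UQ scores tie exactly)"
    } else {
      sprintf("  Final risk class: %s", r$final_class)
    },
    if (!is.null(r$traffic_light) && !is.na(r$traffic_light)) {
      sprintf("  Traffic light: %s (%s)", r$traffic_light,
              traffic_light_phrase[[r$traffic_light]])
    },
    if (!identical(r$final_class, "INDETERMINATE") &&
        !identical(r$final_class, r$predicted_class)) {
      sprintf("  Note: classifier prediction (%s) and distance-based final class (%s) disagree.",
              r$predicted_class, r$final_class)
    })
  paste(lines[!vapply(lines, is.null, logical(1L))], collapse = "\n")
}
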