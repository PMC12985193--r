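#' Decision configuration for a binary probabilistic classifier
#'
#' @param threshold Probability cut-off in (0, 1); a positive-class
#'   probability at or above it predicts the positive label.
#' @param calibration_rule How the threshold was obtained: `"fixed"` (user
#'   supplied) or `"event-rate"` (set to the training prevalence of the
#'   positive class, a standard mitigation for class imbalance).
#' @param positive_label Label predicted when the threshold is met.
#' @return Object of class `decision_config`.
#' @export
decision_config <- function(threshold, calibration_rule = "fixed",
                            positive_label = "HR") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  structure(list(threshold = threshold, calibration_rule = calibration_rule,
                 positive_label = positive_label),
            class = "decision_config")
}

#' Calibrate the decision threshold to the training event rate
#'
#' Sets the probability cut-off equal to the prevalence of the positive class
#' in the training labels. With imbalanced cohorts a 0.5 cut-off under-calls
#' the minority class; thresholding at the event rate restores sensible
#' operating behaviour without retraining. The threshold must be computed
#' from training labels only, never from test cases.
#'
#' @param labels Character/factor vector of training labels containing both
#'   classes.
#' @param positive_label Which label counts as positive (default `"HR"`).
#' @return A [decision_config()] with `calibration_rule = "event-rate"`.
#' @export
#' @examples
#' calibrate_threshold(rep(c("HR", "LR"), c(36, 64))) # threshold 0.36
calibrate_threshold <- function(labels, positive_label = "HR") {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("event-rate calibration needs both classes in the label vector",
         call. = FALSE)
  }
  decision_config(mean(labels == positive_label),
                  calibration_rule = "event-rate",
                  positive_label = positive_label)
}

#' Predict the risk class from a positive-class probability
#'
#' Boundary-inclusive on the positive side: a probability exactly equal to
#' the threshold predicts the positive label.
#'
#' @param probability_positive Probability (or vector of probabilities) of
#'   the positive class, in \[0, 1\].
#' @param config A [decision_config()].
#' @param negative_label Label returned below the threshold.
#' @return Character vector of predicted labels.
#' @export
#' @examples
#' cfg <- decision_config(0.36)
#' predict_class(c(0.48, 0.10), cfg) # "HR" "LR"
predict_class <- function(probability_positive, config,
                          negative_label = "LR") {
  p <- probability_positive
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p >= config$threshold, config$positive_label, negative_label)
}

#' Fit a reference logistic-regression classifier on a labelled cohort
#'
#' A plain linear-in-features logistic regression, provided so the scoring
#' pipeline can run without externally supplied probabilities. The
#' uncertainty layer is classifier-agnostic: any function mapping a feature
#' matrix to positive-class probabilities can replace this one, and
#' precomputed probabilities in the input table bypass fitting entirely.
#' The fit is deterministic (no stochastic optimisation).
#'
#' @param cohort A [labeled_cohort()] with at least 2 cases per class.
#' @return A function `f(newdata)` taking a feature matrix/data frame on the
#'   original (unscaled) feature scale and returning positive-class
#'   probabilities in \[0, 1\]. The cohort's fitted feature scaling is applied
#'   internally.
#' @export
fit_reference_classifier <- function(cohort) {
  counts <- table(factor(cohort$labels, levels = cohort$label_names))
  if (any(counts < 2L)) {
    stop("classifier fit needs >= 2 cases per class", call. = FALSE)
  }
  X <- cohort$features
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop("degenerate (constant) feature(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  y <- as.integer(cohort$labels == cohort$label_names[["positive"]])
  df <- data.frame(.y = y, X, check.names = FALSE)
  # perfectly separable demo cohorts legitimately drive fitted probabilities
  # to 0/1; the resulting glm warning is expected, not a failure
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  feature_names <- cohort$feature_names
  scaling <- cohort$scaling
  function(newdata) {
    M <- as.matrix(as.data.frame(newdata)[, feature_names, drop = FALSE])
    storage.mode(M) <- "double"
    M <- apply_scaling(M, scaling)
    p <- stats::predict(fit, newdata = as.data.frame(M), type = "response")
    unname(pmin(pmax(p, 0), 1))
  }
}
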