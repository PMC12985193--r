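#' Distance-ratio epistemic uncertainty score
#'
#' Scores a candidate label from two nearest-neighbour distances:
#' `d_own`, the case's distance to the nearest training example carrying the
#' candidate label, and `d_reference`, the reference distance (by default the
#' nearest opposite-label training example). The score is
#'
#' \deqn{U = d_{own} \cdot \frac{d_{own}}{d_{ref}} = d_{own}^2 / d_{ref}}
#'
#' so it grows with the absolute distance to the label and with the distance
#' relative to the competing label. 0 is perfect certainty — the training set
#' contains a case with identical features. Two edge cases are defined
#' explicitly: `d_own = 0` scores 0 even when `d_reference = 0` (an exact
#' training duplicate is maximal certainty), while `d_own > 0` with
#' `d_reference = 0` scores `Inf` (the case coincides with an opposite-label
#' training example — maximal uncertainty for this label).
#'
#' @param d_own Nonnegative distance(s) to the nearest same-label training
#'   case(s).
#' @param d_reference Nonnegative reference distance(s).
#' @return Nonnegative score(s), possibly `Inf`; vectorized over both
#'   arguments.
#' @export
#' @examples
#' uq_score(0.19, 0.28) # ~0.13
#' uq_score(0, 0)       # 0: exact training duplicate
uq_score <- function(d_own, d_reference) {
  if (any(d_own < 0) || any(d_reference < 0)) {
    stop("distances must be nonnegative", call. = FALSE)
  }
  n <- max(length(d_own), length(d_reference))
  d_own <- rep_len(d_own, n)
  d_reference <- rep_len(d_reference, n)
  out <- d_own^2 / d_reference     # 0/0 and x/0 fixed up below
  out[d_own == 0] <- 0
  out[d_own > 0 & d_reference == 0] <- Inf
  as.numeric(out)
}

#' Score both candidate labels and select the final risk class
#'
#' Applies [uq_score()] to each candidate label of a case and picks the final
#' class as the label with the strictly smaller score (the score nearest 0).
#' Exact ties yield `"INDETERMINATE"` rather than a silent default.
#'
#' Two reference-distance conventions are supported, recorded in the result:
#' \describe{
#'   \item{`"opposite-label"` (default)}{each label's reference is the
#'     nearest opposite-label distance: `U_neg = d_neg^2 / d_pos`,
#'     `U_pos = d_pos^2 / d_neg`. This is the convention under which the
#'     package's worked examples reproduce.}
#'   \item{`"global-min"`}{both labels share `a = min(d_neg, d_pos)` as the
#'     reference, so the nearer label always scores exactly its own distance.}
#' }
#'
#' @param nd A `neighbor_distances` tibble (from [neighbor_distances()]), or
#'   any data frame with columns `case_id`, `d_negative`, `d_positive`.
#' @param variant `"opposite-label"` or `"global-min"`.
#' @param label_names Named character vector `c(negative=, positive=)`.
#' @return Tibble of class `uq_result`: `case_id`, `uq_negative`,
#'   `uq_positive`, `reference_distance_negative`,
#'   `reference_distance_positive`, `final_class`, `formula_variant`.
#' @export
score_cases <- function(nd, variant = c("opposite-label", "global-min"),
                        label_names = c(negative = "LR", positive = "HR")) {
  variant <- match.arg(variant)
  label_names <- normalize_label_names(label_names)
  dn <- nd$d_negative
  dp <- nd$d_positive
  if (any(!is.finite(dn) & !is.finite(dp))) {
    stop("both per-label distances are non-finite for at least one case; ",
         "the upstream cohort must contain both labels", call. = FALSE)
  }
  if (variant == "opposite-label") {
    ref_n <- dp
    ref_p <- dn
  } else {
    ref_n <- ref_p <- pmin(dn, dp)
  }
  un <- uq_score(dn, ref_n)
  up <- uq_score(dp, ref_p)
  final <- ifelse(un < up, label_names[["negative"]],
                  ifelse(up < un, label_names[["positive"]], "INDETERMINATE"))
  structure(tibble::tibble(case_id = nd$case_id,
                           uq_negative = un, uq_positive = up,
                           reference_distance_negative = ref_n,
                           reference_distance_positive = ref_p,
                           final_class = final,
                           formula_variant = variant),
            class = c("uq_result", class(tibble::tibble())))
}

#' Score a single case from its two per-label distances
#'
#' Convenience scalar wrapper around [score_cases()].
#'
#' @param d_negative,d_positive Nonnegative per-label nearest-neighbour
#'   distances.
#' @inheritParams score_cases
#' @param case_id Identifier carried into the result.
#' @return One-row `uq_result` tibble.
#' @export
#' @examples
#' score_case(d_negative = 0.19, d_positive = 0.28)
score_case <- function(d_negative, d_positive,
                       variant = c("opposite-label", "global-min"),
                       label_names = c(negative = "LR", positive = "HR"),
                       case_id = "case") {
  score_cases(tibble::tibble(case_id = case_id, d_negative = d_negative,
                             d_positive = d_positive),
              variant = variant, label_names = label_names)
}
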