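#' ROC curve over depletion scores
#'
#' Builds the full receiver operating characteristic for the rule
#' "depletion >= threshold is called sensitizer". Candidate thresholds are
#' the midpoints between consecutive distinct sorted scores, plus one
#' threshold below the minimum (everything positive) and one above the
#' maximum (everything negative), so every achievable confusion matrix is
#' represented exactly once.
#'
#' @param scores numeric vector of percent depletion values.
#' @param labels hazard labels (`"sensitizer"` / `"non_sensitizer"`), or a
#'   logical vector with `TRUE` = sensitizer.
#' @return object of class `pr_roc`: a tibble with columns `threshold`,
#'   `tpr`, `fpr`, `youden_j`, carrying `scores` and `labels` as attributes.
#' @export
roc_curve <- function(scores, labels) {
  if (is.logical(labels)) {
    labels <- ifelse(labels, "sensitizer", "non_sensitizer")
  }
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% hazard_levels)) {
    stop("labels must be 'sensitizer' or 'non_sensitizer'", call. = FALSE)
  }
  pos <- labels == "sensitizer"
  if (!any(pos) || all(pos)) {
    stop("degenerate data: both classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1,
                  if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
                  s[length(s)] + 1)
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  out <- tibble::tibble(threshold = thresholds, tpr = tpr, fpr = fpr,
                        youden_j = tpr - fpr)
  attr(out, "scores") <- scores
  attr(out, "labels") <- labels
  class(out) <- c("pr_roc", class(out))
  out
}

#' Optimal classification cut-off from a ROC curve
#'
#' Selects the threshold maximising Youden's J = sensitivity + specificity
#' \eqn{-} 1 (equivalently, balanced accuracy: the two criteria always pick
#' the same thresholds). Ties are broken towards higher specificity, then
#' towards the larger threshold, favouring the more conservative cut-off.
#' Because any threshold between the same two neighbouring scores induces the
#' same classification, the result reports the whole open tie interval of
#' equivalent cut-offs alongside the representative midpoint.
#'
#' @param curve a [roc_curve()].
#' @param criterion `"youden"` or `"balanced_accuracy"` (equivalent maxima).
#' @return object of class `pr_cutoff`: list with `threshold`, `criterion`,
#'   `achieved_sensitivity`, `achieved_specificity`,
#'   `achieved_balanced_accuracy`, `youden_j` and `tie_interval`
#'   (open interval `c(lo, hi)` of thresholds inducing the same confusion
#'   matrix).
#' @export
optimal_cutoff <- function(curve, criterion = c("youden", "balanced_accuracy")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "pr_roc"))
  j <- curve$youden_j
  best <- which(j >= max(j) - 1e-12)
  # tie-break: higher specificity (lower fpr), then larger threshold
  best <- best[order(curve$fpr[best], -curve$threshold[best])]
  pick <- best[1]
  thr <- curve$threshold[pick]
  s <- sort(unique(attr(curve, "scores")))
  lo <- if (any(s < thr)) max(s[s < thr]) else -Inf
  hi <- if (any(s >= thr)) min(s[s >= thr]) else Inf
  structure(
    list(threshold = thr,
         criterion = criterion,
         achieved_sensitivity = curve$tpr[pick],
         achieved_specificity = 1 - curve$fpr[pick],
         achieved_balanced_accuracy =
           (curve$tpr[pick] + 1 - curve$fpr[pick]) / 2,
         youden_j = j[pick],
         tie_interval = c(lo, hi)),
    class = "pr_cutoff"
  )
}

#' @export
print.pr_cutoff <- function(x, ...) {
  cat(sprintf(
    "Optimal cut-off (%s): %.4f%%  [equivalent on (%.4g, %.4g)]\n",
    x$criterion, x$threshold, x$tie_interval[1], x$tie_interval[2]))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  balanced accuracy %.3f\n",
              x$achieved_sensitivity, x$achieved_specificity,
              x$achieved_balanced_accuracy))
  invisible(x)
}
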