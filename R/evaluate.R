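#' Round half away from zero
#'
#' Commercial (half-up) rounding: 74.5 becomes 75. Used for reporting metric
#' percentages, where R's default round-half-even would disagree with the
#' published tables on exact .5 cases.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion matrix and performance metrics
#'
#' Counts true/false positives and negatives of a hazard prediction against
#' truth ("sensitizer" is the positive class) and derives
#' accuracy = (TP + TN) / n, sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP) and balanced accuracy =
#' (sensitivity + specificity) / 2. Metrics whose denominator is empty (a
#' truth class absent) are reported as `NA` rather than silently zero.
#'
#' @param predicted,truth hazard-label vectors of equal length; `predicted`
#'   may also be a [predict_all()] result, in which case its own `truth`
#'   column is used when `truth` is missing.
#' @return object of class `confusion_summary`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn`, `n`, proportions `accuracy`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`, and `rounded_pct`
#'   (the four metrics as half-up-rounded integer percents).
#' @export
confusion <- function(predicted, truth = NULL) {
  if (is.data.frame(predicted)) {
    if (is.null(truth)) truth <- predicted$truth
    predicted <- predicted$predicted
  }
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!all(c(predicted, truth) %in% hazard_levels)) {
    stop("labels must be 'sensitizer' or 'non_sensitizer'", call. = FALSE)
  }
  p <- predicted == "sensitizer"
  t <- truth == "sensitizer"
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  n <- length(truth)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  ba <- (sens + spec) / 2
  rounded <- round_half_up(100 * c(accuracy = acc, balanced_accuracy = ba,
                                   sensitivity = sens, specificity = spec))
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n = n,
         accuracy = acc, balanced_accuracy = ba,
         sensitivity = sens, specificity = spec,
         rounded_pct = rounded),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("n = %d   TP %d  FP %d  FN %d  TN %d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("accuracy %s%%  balanced accuracy %s%%  sensitivity %s%%  specificity %s%%\n",
              x$rounded_pct[["accuracy"]], x$rounded_pct[["balanced_accuracy"]],
              x$rounded_pct[["sensitivity"]], x$rounded_pct[["specificity"]]))
  invisible(x)
}

#' Evaluate one prediction model on a chemicals dataset
#'
#' Composition of [predict_all()], [binarize_human_category()] and
#' [confusion()].
#'
#' @inheritParams predict_all
#' @return a [confusion()] summary.
#' @export
evaluate_model <- function(records, assay = c("protreact", "dpra"), model) {
  confusion(predict_all(records, assay, model))
}

#' Performance grid for the four published model columns
#'
#' Evaluates the two assays' single-branch models (spectrophotometric
#' cysteine and mean rules; DPRA cysteine and mean rules) and lays the four
#' reporting metrics out as a model-by-metric grid of half-up-rounded integer
#' percents.
#'
#' @param records chemicals tibble (default: the bundled dataset).
#' @return tibble with columns `metric` and one column per model.
#' @export
performance_table <- function(records = pr_chemicals()) {
  models <- list(
    protreact_cys = list("protreact", protreact_cys_model()),
    protreact_mean = list("protreact", protreact_mean_model()),
    dpra_cys = list("dpra", dpra_cys_model()),
    dpra_mean = list("dpra", dpra_mean_model())
  )
  cols <- lapply(models, function(m) {
    evaluate_model(records, m[[1]], m[[2]])$rounded_pct
  })
  out <- tibble::tibble(metric = c("accuracy", "balanced_accuracy",
                                   "sensitivity", "specificity"))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
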