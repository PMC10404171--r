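#' Define a hazard prediction model
#'
#' A prediction model is a rule over a chemical's depletion profile: a branch
#' (`cys_only`, `mean_only` or `combined_or`), one threshold per consulted
#' statistic, and the comparison strictness at the threshold (`inclusive`
#' means depletion >= threshold calls a sensitizer; `strict` requires >).
#' A chemical that fails every consulted rule is a non-sensitizer.
#'
#' @param name model label used in reports.
#' @param branch which depletion statistic(s) the rule consults.
#' @param cys_threshold,mean_threshold percent thresholds in \[0, 100\];
#'   required by the branches that consult them.
#' @param comparison boundary semantics at the threshold.
#' @return object of class `prediction_model`.
#' @seealso [protreact_cys_model()] and friends for the published models.
#' @export
prediction_model <- function(name,
                             branch = c("cys_only", "mean_only", "combined_or"),
                             cys_threshold = NULL, mean_threshold = NULL,
                             comparison = c("inclusive", "strict")) {
  branch <- match.arg(branch)
  comparison <- match.arg(comparison)
  needs_cys <- branch %in% c("cys_only", "combined_or")
  needs_mean <- branch %in% c("mean_only", "combined_or")
  check_thr <- function(x, what) {
    if (is.null(x)) stop(branch, " model requires ", what, call. = FALSE)
    if (!is.numeric(x) || length(x) != 1L || x < 0 || x > 100) {
      stop(what, " must be a percent in [0, 100]", call. = FALSE)
    }
    x
  }
  structure(
    list(name = name, branch = branch,
         cys_threshold = if (needs_cys)
           check_thr(cys_threshold, "cys_threshold") else NULL,
         mean_threshold = if (needs_mean)
           check_thr(mean_threshold, "mean_threshold") else NULL,
         comparison = comparison),
    class = "prediction_model"
  )
}

#' Published prediction models
#'
#' Ready-made configurations of the two assays' published rules. The
#' spectrophotometric (ProtReact) models use inclusive comparisons:
#' cysteine depletion >= 13.935% or mean depletion >= 9.563% calls a
#' sensitizer. The DPRA models use strict comparisons: mean depletion
#' > 6.38%, or cysteine depletion > 13.89% when only the cysteine run is
#' usable (the cysteine-only fallback covers lysine co-elution, which the
#' caller decides; no co-elution detection is modelled here).
#'
#' @return a [prediction_model()].
#' @export
protreact_cys_model <- function() {
  prediction_model("ProtReact Cys >= 13.935%", "cys_only",
                   cys_threshold = 13.935, comparison = "inclusive")
}

#' @rdname protreact_cys_model
#' @export
protreact_mean_model <- function() {
  prediction_model("ProtReact Mean >= 9.563%", "mean_only",
                   mean_threshold = 9.563, comparison = "inclusive")
}

#' @rdname protreact_cys_model
#' @export
protreact_combined_model <- function() {
  prediction_model("ProtReact Cys >= 13.935% | Mean >= 9.563%", "combined_or",
                   cys_threshold = 13.935, mean_threshold = 9.563,
                   comparison = "inclusive")
}

#' @rdname protreact_cys_model
#' @export
dpra_cys_model <- function() {
  prediction_model("DPRA Cys > 13.89%", "cys_only",
                   cys_threshold = 13.89, comparison = "strict")
}

#' @rdname protreact_cys_model
#' @export
dpra_mean_model <- function() {
  prediction_model("DPRA Mean > 6.38%", "mean_only",
                   mean_threshold = 6.38, comparison = "strict")
}

#' Predict hazard from depletion values
#'
#' Applies a prediction model to cysteine and/or mean depletion values.
#' Values are compared as supplied: published tables may contain negative
#' (unclamped) entries, which any positive threshold classifies as
#' non-sensitizer, so no re-clamping is applied here.
#'
#' @param model a [prediction_model()].
#' @param cys,mean percent depletion vectors; only the branch's required
#'   statistic(s) must be supplied.
#' @return tibble with columns `predicted` (hazard label) and
#'   `triggering_rule` (`"cys"`, `"mean"`, `"both"`, or `"none"`).
#' @examples
#' predict_hazard(protreact_cys_model(), cys = c(62.0, 13.7))
#' @export
predict_hazard <- function(model, cys = NULL, mean = NULL) {
  stopifnot(inherits(model, "prediction_model"))
  cmp <- if (model$comparison == "inclusive") `>=` else `>`
  needs_cys <- model$branch %in% c("cys_only", "combined_or")
  needs_mean <- model$branch %in% c("mean_only", "combined_or")
  if (needs_cys && (is.null(cys) || anyNA(cys))) {
    stop("model '", model$name, "' requires cysteine depletion values",
         call. = FALSE)
  }
  if (needs_mean && (is.null(mean) || anyNA(mean))) {
    stop("model '", model$name, "' requires mean depletion values",
         call. = FALSE)
  }
  n <- max(length(cys), length(mean))
  cys_hit <- if (needs_cys) cmp(cys, model$cys_threshold) else rep(FALSE, n)
  mean_hit <- if (needs_mean) cmp(mean, model$mean_threshold) else rep(FALSE, n)
  predicted <- ifelse(cys_hit | mean_hit, "sensitizer", "non_sensitizer")
  rule <- ifelse(cys_hit & mean_hit, "both",
                 ifelse(cys_hit, "cys", ifelse(mean_hit, "mean", "none")))
  tibble::tibble(predicted = predicted, triggering_rule = rule)
}

#' Predict hazard for every chemical in a dataset
#'
#' Applies one prediction model to one assay's depletion columns of a
#' chemicals table (see [load_chemicals()]), preserving row order.
#'
#' @param records chemicals tibble.
#' @param assay `"protreact"` or `"dpra"`; selects the depletion columns.
#' @param model a [prediction_model()].
#' @return tibble with columns `index`, `name`, `assay`, `branch`,
#'   `predicted`, `triggering_rule`, `truth`.
#' @export
predict_all <- function(records, assay = c("protreact", "dpra"), model) {
  assay <- match.arg(assay)
  if (nrow(records) == 0L) {
    return(tibble::tibble(index = integer(0), name = character(0),
                          assay = character(0), branch = character(0),
                          predicted = character(0),
                          triggering_rule = character(0),
                          truth = character(0)))
  }
  prefix <- if (assay == "protreact") "pr" else "dpra"
  pred <- predict_hazard(model,
                         cys = records[[paste0(prefix, "_cys")]],
                         mean = records[[paste0(prefix, "_mean")]])
  tibble::tibble(
    index = records$index, name = records$name,
    assay = assay, branch = model$branch,
    predicted = pred$predicted, triggering_rule = pred$triggering_rule,
    truth = binarize_human_category(records$human_category)
  )
}
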