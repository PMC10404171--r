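#' Chemical-by-chemical comparison of two prediction models
#'
#' Runs two (assay, model) pairs over the same dataset and reports how their
#' errors overlap: per-model correct counts, the number of chemicals correct
#' under both, and the false-positive / false-negative rosters with their
#' intersections. Rosters are sorted by chemical index so they can be diffed
#' mechanically against a published comparison table.
#'
#' @param records chemicals tibble.
#' @param assay_a,assay_b `"protreact"` or `"dpra"`.
#' @param model_a,model_b [prediction_model()] objects.
#' @return object of class `concordance_report`: list with `n`, `correct_a`,
#'   `correct_b`, `correct_both` (plus its split `correct_both_sens` /
#'   `correct_both_nonsens`), and roster tibbles (`index`, `name`) `fp_a`,
#'   `fp_b`, `fp_common`, `fn_a`, `fn_b`, `fn_common`.
#' @export
compare_models <- function(records, assay_a, model_a, assay_b, model_b) {
  pa <- predict_all(records, assay_a, model_a)
  pb <- predict_all(records, assay_b, model_b)
  truth <- pa$truth
  roster <- function(idx) {
    tibble::tibble(index = records$index[idx], name = records$name[idx])[
      order(records$index[idx]), ]
  }
  fp_a <- truth == "non_sensitizer" & pa$predicted == "sensitizer"
  fp_b <- truth == "non_sensitizer" & pb$predicted == "sensitizer"
  fn_a <- truth == "sensitizer" & pa$predicted == "non_sensitizer"
  fn_b <- truth == "sensitizer" & pb$predicted == "non_sensitizer"
  ok_a <- pa$predicted == truth
  ok_b <- pb$predicted == truth
  structure(
    list(n = nrow(records),
         model_a = model_a$name, model_b = model_b$name,
         correct_a = sum(ok_a), correct_b = sum(ok_b),
         correct_both = sum(ok_a & ok_b),
         correct_both_sens = sum(ok_a & ok_b & truth == "sensitizer"),
         correct_both_nonsens = sum(ok_a & ok_b & truth == "non_sensitizer"),
         fp_a = roster(which(fp_a)), fp_b = roster(which(fp_b)),
         fp_common = roster(which(fp_a & fp_b)),
         fn_a = roster(which(fn_a)), fn_b = roster(which(fn_b)),
         fn_common = roster(which(fn_a & fn_b))),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d chemicals\n  A: %s\n  B: %s\n",
              x$n, x$model_a, x$model_b))
  cat(sprintf("  correct: A %d, B %d, both %d (%d S + %d NS)\n",
              x$correct_a, x$correct_b, x$correct_both,
              x$correct_both_sens, x$correct_both_nonsens))
  cat(sprintf("  false positives: A %d, B %d, common %d\n",
              nrow(x$fp_a), nrow(x$fp_b), nrow(x$fp_common)))
  cat(sprintf("  false negatives: A %d, B %d, common %d\n",
              nrow(x$fn_a), nrow(x$fn_b), nrow(x$fn_common)))
  invisible(x)
}

#' Per-domain correctness tally for two models
#'
#' Counts, within each mechanistic domain, how many chemicals each model
#' classifies correctly. Every chemical must carry a domain annotation;
#' compound assignments are represented by their primary token (see
#' [load_domains()]).
#'
#' @param records chemicals tibble.
#' @param domains domain tibble with `index` and `domain` covering all
#'   records.
#' @param predictions_a,predictions_b [predict_all()] results for the two
#'   models.
#' @return tibble with columns `domain`, `correct_a`, `correct_b`, `total`,
#'   sorted by descending `total`.
#' @export
domain_tally <- function(records, domains, predictions_a, predictions_b) {
  missing <- setdiff(records$index, domains$index)
  if (length(missing)) {
    stop("missing domain annotation for chemical index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dom <- domains$domain[match(records$index, domains$index)]
  ok_a <- predictions_a$predicted == predictions_a$truth
  ok_b <- predictions_b$predicted == predictions_b$truth
  agg <- function(x) tapply(x, dom, sum)
  tot <- tapply(rep(1L, length(dom)), dom, sum)
  out <- tibble::tibble(
    domain = names(tot),
    correct_a = as.integer(agg(ok_a)[names(tot)]),
    correct_b = as.integer(agg(ok_b)[names(tot)]),
    total = as.integer(tot)
  )
  out[order(-out$total), ]
}
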