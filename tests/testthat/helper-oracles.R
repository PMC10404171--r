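# Independent oracles and tiny fixture builders shared across test files.

# Brute-force ROC: evaluate the ">= t -> sensitizer" rule at every distinct
# score (and one threshold below all scores), by direct counting. Kept
# deliberately naive and separate from roc_curve().
brute_force_best <- function(scores, labels) {
  pos <- labels == "sensitizer"
  cand <- c(min(scores) - 1, sort(unique(scores)), max(scores) + 1)
  pts <- t(vapply(cand, function(t) {
    c(tpr = sum(scores[pos] >= t) / sum(pos),
      fpr = sum(scores[!pos] >= t) / sum(!pos))
  }, numeric(2)))
  j <- pts[, "tpr"] - pts[, "fpr"]
  keep <- j >= max(j) - 1e-12
  # all tied optima; callers check membership
  list(j = max(j), tpr = pts[keep, "tpr"], fpr = pts[keep, "fpr"],
       threshold = cand[keep])
}

# confusion counts by direct table(), independent of confusion()
brute_counts <- function(predicted, truth) {
  c(tp = sum(predicted == "sensitizer" & truth == "sensitizer"),
    fp = sum(predicted == "sensitizer" & truth == "non_sensitizer"),
    fn = sum(predicted == "non_sensitizer" & truth == "sensitizer"),
    tn = sum(predicted == "non_sensitizer" & truth == "non_sensitizer"))
}

# minimal valid chemicals table for structural tests
toy_chemicals <- function(n = 4) {
  k <- seq_len(n)
  tibble::tibble(
    index = k,
    name = paste0("chem", k),
    cas = sprintf("%02d-00-%d", 10 + k, k %% 10),
    human_category = rep(c(2L, 6L), length.out = n),
    domain = NA_character_, prohapten_flag = NA_character_,
    pr_cys = rep(c(80, 1), length.out = n),
    pr_lys = rep(c(60, 0), length.out = n),
    pr_mean = rep(c(70, 0.5), length.out = n),
    dpra_cys = rep(c(90, 2), length.out = n),
    dpra_lys = rep(c(50, 1), length.out = n),
    dpra_mean = rep(c(70, 1.5), length.out = n)
  )
}

expected_fp_a <- c(72, 76, 79, 88, 105)
expected_fp_b <- c(73, 76, 80, 85, 88, 92, 100, 104, 105)
expected_fn_common <- c(10, 24, 34, 35, 48, 52, 54, 55, 60, 61, 67)
expected_fn_a <- sort(c(expected_fn_common,
                        c(2, 6, 11, 21, 38, 41, 42, 44, 56, 62, 66)))
expected_fn_b <- sort(c(expected_fn_common,
                        c(31, 37, 49, 51, 53, 65, 69, 70)))
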