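#!/usr/bin/env Rscript
# Chemical-by-chemical comparison of the two assays' headline rules
# (spectrophotometric cysteine-only vs DPRA mean) against the human labels:
# correct counts, shared and assay-specific errors, and per-domain tallies.

library(protreact)

dir.create("results", showWarnings = FALSE)
chem <- pr_chemicals()
dom <- pr_domains()

model_a <- protreact_cys_model()
model_b <- dpra_mean_model()
rep <- compare_models(chem, "protreact", model_a, "dpra", model_b)
print(rep)

rosters <- rbind(
  cbind(set = "fp_protreact", rep$fp_a), cbind(set = "fp_dpra", rep$fp_b),
  cbind(set = "fp_common", rep$fp_common),
  cbind(set = "fn_protreact", rep$fn_a), cbind(set = "fn_dpra", rep$fn_b),
  cbind(set = "fn_common", rep$fn_common))
utils::write.csv(rosters, "results/error_rosters.csv", row.names = FALSE)

pa <- predict_all(chem, "protreact", model_a)
pb <- predict_all(chem, "dpra", model_b)
tal <- domain_tally(chem, dom, pa, pb)
print(as.data.frame(tal))
message("no-alert chemicals: ", tal$correct_a[tal$domain == "none"], "/",
        tal$total[tal$domain == "none"], " correct (ProtReact) vs ",
        tal$correct_b[tal$domain == "none"], "/35 (DPRA); acyl transfers: ",
        tal$correct_b[tal$domain == "acyl_transfer"], "/9 (DPRA) vs ",
        tal$correct_a[tal$domain == "acyl_transfer"], "/9 (ProtReact)")
utils::write.csv(tal, "results/domain_breakdown.csv", row.names = FALSE)

# shared false negatives are enriched in pre/pro-haptens, which need abiotic
# or metabolic activation the cell-free assays cannot supply
common_fn <- dom[dom$index %in% rep$fn_common$index, ]
message(sum(nzchar(common_fn$prohapten_flag) & !is.na(common_fn$prohapten_flag)),
        " of ", nrow(common_fn), " shared false negatives carry a ",
        "pre/pro-hapten flag")
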