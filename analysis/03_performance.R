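#!/usr/bin/env Rscript
# Hazard-prediction performance of the four single-branch models on the
# 106-chemical benchmark: accuracy, balanced accuracy, sensitivity and
# specificity as half-up-rounded integer percents.

library(protreact)

dir.create("results", showWarnings = FALSE)
chem <- pr_chemicals()

grid <- performance_table(chem)
print(as.data.frame(grid))
message("spectrophotometric cysteine rule reaches the best accuracy (",
        grid$protreact_cys[grid$metric == "accuracy"],
        "%) and specificity (",
        grid$protreact_cys[grid$metric == "specificity"],
        "%); the DPRA mean rule is the most sensitive (",
        grid$dpra_mean[grid$metric == "sensitivity"], "%)")
utils::write.csv(grid, "results/performance.csv", row.names = FALSE)
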