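#!/usr/bin/env Rscript
# Benchmark dataset overview: composition of the 106-chemical panel and the
# internal consistency of the published depletion columns.

library(protreact)

dir.create("results", showWarnings = FALSE)
chem <- pr_chemicals()

message(nrow(chem), " chemicals; ",
        sum(chem$hazard == "sensitizer"), " sensitizers / ",
        sum(chem$hazard == "non_sensitizer"), " non-sensitizers after the",
        " category 1-4 vs 5-6 binarization")

tally <- as.data.frame(table(human_category = chem$human_category))
print(tally)

incons <- chem[chem$pr_mean_inconsistent | chem$dpra_mean_inconsistent,
               c("index", "name", "pr_cys", "pr_lys", "pr_mean")]
message("rows whose published mean disagrees with (cys+lys)/2, kept as ",
        "published: ", paste(incons$name, collapse = ", "))

utils::write.csv(tally, "results/category_tally.csv", row.names = FALSE)
utils::write.csv(incons, "results/mean_inconsistent_rows.csv",
                 row.names = FALSE)

dom <- pr_domains()
domtab <- as.data.frame(table(domain = dom$domain))
message("mechanistic-domain composition (synthetic reconstruction of the ",
        "supplement): ",
        paste(domtab$domain, domtab$Freq, sep = "=", collapse = ", "))
utils::write.csv(domtab, "results/domain_composition.csv", row.names = FALSE)
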