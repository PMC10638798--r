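#!/usr/bin/env Rscript
# Step 1 — build the synthetic model inputs.
#
# Two inputs of the analysis are not shipped with real data: the national
# background-mortality schedule and the patient-level surgical cost registry
# (confidential). This script generates their synthetic stand-ins, estimates
# the per-arm baseline costs by splitting lumpectomies at the DRG reference
# cost of 36,439 SEK, and writes everything under results/.

suppressPackageStartupMessages(library(insituCEA))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1
dir.create("results", showWarnings = FALSE)

lifetable <- generate_lifetable()
write_lifetable(lifetable, "results/lifetable.csv")
cat(sprintf("Life table: ages %d-%d, q(58) = %.4f, q(85) = %.4f\n",
            min(lifetable$age), max(lifetable$age),
            mortality_at(lifetable, 58), mortality_at(lifetable, 85)))

registry <- generate_registry(seed = seed)
utils::write.csv(registry, "results/registry.csv", row.names = FALSE)
cat(sprintf("Registry: %d patients (%d mastectomy, %d lumpectomy)\n",
            nrow(registry), sum(registry$surgery == "mastectomy"),
            sum(registry$surgery == "lumpectomy")))

est <- estimate_baseline_costs(registry)
utils::write.csv(est, "results/baseline_costs.csv", row.names = FALSE)
cat("\nBaseline cost estimates after the DRG split (SEK, 2020):\n")
print(est, row.names = FALSE)
cat("\nPublished comparators: 87,670 / 27,655 / 50,352 SEK",
    "with counts 96 / 240 / 389.\n")
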