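#!/usr/bin/env Rscript
# Step 3 — probabilistic sensitivity analysis.
#
# 1,000 Monte Carlo draws from the published parameter distributions, one
# cohort run per strategy per draw (common parameters within a draw),
# summarised as means with 95% percentile intervals, CE-plane point clouds
# for each pairwise comparison and CEAC curves for lumpectomy with vs
# without irradiation under both perspectives. Figures are written when
# ggplot2 is available.

suppressPackageStartupMessages(library(insituCEA))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1
n_iter <- if (length(i <- which(args == "--n-iter"))) as.integer(args[i + 1]) else 1000
dir.create("results", showWarnings = FALSE)

params <- default_parameters()
lifetable <- if (file.exists("results/lifetable.csv")) {
  read_lifetable("results/lifetable.csv")
} else {
  generate_lifetable()
}

psa <- suppressWarnings(run_psa(params, lifetable, n_iter = n_iter, seed = seed))
utils::write.csv(psa$draws, "results/psa_draws.csv", row.names = FALSE)
utils::write.csv(psa$summary, "results/psa_summary.csv", row.names = FALSE)
print(psa)

cat("\nIncremental analysis on PSA means (healthcare):\n")
print(psa_incremental(psa, "healthcare"))

pairs <- list(c("mastectomy", "lumpectomy_no_rt"),
              c("mastectomy", "lumpectomy_rt"),
              c("lumpectomy_rt", "lumpectomy_no_rt"))
planes <- do.call(rbind, lapply(pairs, function(cmp) {
  inc <- ce_plane(psa, cmp, "healthcare")
  inc$comparison <- paste(cmp[1], "vs", cmp[2])
  inc
}))
utils::write.csv(planes, "results/ce_plane_healthcare.csv", row.names = FALSE)

cmp <- c("lumpectomy_rt", "lumpectomy_no_rt")
curves <- rbind(
  cbind(as.data.frame(ceac(psa, cmp, perspective = "healthcare")),
        perspective = "healthcare"),
  cbind(as.data.frame(ceac(psa, cmp, perspective = "societal")),
        perspective = "societal")
)
utils::write.csv(curves, "results/ceac_lumpectomy_rt_vs_no_rt.csv",
                 row.names = FALSE)
cat("\nCEAC, lumpectomy+RT vs lumpectomy-RT:\n")
print(utils::head(reshape(curves, idvar = "wtp", timevar = "perspective",
                          direction = "wide"), 21), row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/ce_plane.png",
         ggplot(planes, aes(d_qaly, d_cost / 1e3)) +
           geom_point(alpha = 0.3, size = 0.6) +
           geom_hline(yintercept = 0, linetype = 2) +
           geom_vline(xintercept = 0, linetype = 2) +
           facet_wrap(~comparison) +
           labs(x = "Incremental QALYs", y = "Incremental cost (1000 SEK)",
                title = "Cost-effectiveness planes (healthcare perspective)"),
         width = 9, height = 3.2, dpi = 150)
  ggsave("results/figures/ceac.png",
         ggplot(curves, aes(wtp / 1e3, probability, colour = perspective)) +
           geom_line() +
           labs(x = "Willingness to pay (1000 SEK/QALY)",
                y = "P(lumpectomy+RT cost-effective)",
                title = "CEAC: lumpectomy with vs without irradiation"),
         width = 6, height = 3.6, dpi = 150)
  cat("\nFigures written to results/figures/\n")
}
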