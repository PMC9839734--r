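#!/usr/bin/env Rscript
# Stage 5: collate the node-set comparison into a single summary table and
# state the ordering findings.

suppressPackageStartupMessages(library(equigrf))

rows <- list()
for (gait in c("walk", "trot")) {
  f <- sprintf("results/pipeline/%s_curve_medians.csv", gait)
  if (!file.exists(f)) stop("run analysis/04_train_evaluate.R first")
  med <- read.csv(f)
  med$gait <- gait
  rows[[gait]] <- med
  pk <- read.csv(sprintf("results/pipeline/%s_peak_agreement.csv", gait))
  best <- pk[which.min(abs(pk$bias) + (pk$upper - pk$lower)), ]
  cat(sprintf(
    "%s: best curve node set %s (median RMSE %.3f N/kg, rho %.4f); ",
    gait, med$node_set[which.min(med$median_rmse)], min(med$median_rmse),
    med$median_rho[which.min(med$median_rmse)]))
  cat(sprintf("tightest peak agreement: %s/%s %s limbs, bias %.3f [%.3f; %.3f].\n",
              best$node_set, best$route, best$limb_pair, best$bias,
              best$lower, best$upper))
}
summary_df <- do.call(rbind, rows)
write.csv(summary_df, "results/05_summary.csv", row.names = FALSE)

for (gait in c("walk", "trot")) {
  med <- rows[[gait]]
  r <- function(ns) med$median_rmse[med$node_set == ns]
  cat(sprintf("%s ordering: All %.3f vs UB %.3f vs Limbs %.3f N/kg -> %s\n",
              gait, r("All"), r("UB"), r("Limbs"),
              if (r("All") <= r("Limbs")) {
                "upper-body information dominates limb timing alone"
              } else "ordering not reproduced at this size"))
}
cat("Wrote results/05_summary.csv.\n")
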