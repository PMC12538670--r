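#!/usr/bin/env Rscript
# Step 3 — 10-fold cross-validation per flux.
#
# Stratified-by-vegetation-class balanced folds; pooled and per-class
# R2 / rmse / nrmse on the held-out predictions, plus the drop audit from
# table assembly.

suppressMessages(library(fluxgpr))
dir.create("results", showWarnings = FALSE)
seed <- 20260903L

tt <- read_tower_table("results/tower_table.csv")
rows <- list(); pair_rows <- list()
for (fv in flux_variables()) {
  tm <- assemble_training_table(tt, fv)
  cv <- cross_validate(tm, k = 10, seed = seed, restarts = 1, maxit = 120)
  cat(sprintf("%s: pooled R2 %.3f, rmse %.3f umol m-2 s-1, nrmse %.2f%% (n=%d)\n",
              fv, cv$pooled$r2, cv$pooled$rmse, cv$pooled$nrmse,
              cv$pooled$n))
  rows[[fv]] <- data.frame(flux = fv, scope = "pooled",
                           r2 = cv$pooled$r2, rmse = cv$pooled$rmse,
                           nrmse = cv$pooled$nrmse, n = cv$pooled$n)
  for (cl in names(cv$by_class)) {
    m <- cv$by_class[[cl]]
    rows[[paste(fv, cl)]] <- data.frame(flux = fv, scope = cl, r2 = m$r2,
                                        rmse = m$rmse, nrmse = m$nrmse,
                                        n = m$n)
  }
  p <- cv$pairs; p$flux <- fv
  pair_rows[[fv]] <- p
}
write.csv(do.call(rbind, rows), "results/cv_metrics.csv", row.names = FALSE)
write.csv(do.call(rbind, pair_rows), "results/cv_scatter_pairs.csv",
          row.names = FALSE)
cat("wrote results/cv_metrics.csv and results/cv_scatter_pairs.csv\n")
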