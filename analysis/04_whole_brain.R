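#!/usr/bin/env Rscript
# Whole-brain analyses: edgewise DBS ON vs OFF signed-rank tests with FDR
# over all 4005 connections, then ON-state PCA connectivity patterns per
# band, elbow-based component selection (100 randomized repetitions), and
# Spearman partial correlations of pattern scores with the five
# neuropsychological T-scores.
suppressMessages(library(dbsconnect))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

cohort <- load_cohort("results/cohort/manifest.json")
covs <- covariate_matrix(cohort$metadata)

edge_hits <- vapply(names(cohort$spec$bands), function(bn) {
  sum(edgewise_on_off_test(cohort, bn)$significant)
}, 0L)
cat("edgewise FDR-significant connections per band (of 4005):\n")
print(edge_hits)

rows <- list(); grids <- list()
for (bn in names(cohort$spec$bands)) {
  pb <- band_pattern_analysis(cohort, bn, covs, seed = seed)
  ve <- pb$pca$variance_explained
  rows[[bn]] <- data.frame(band = bn, n_components = pb$n_selected,
                           top_variance_pct = round(100 * ve[1], 1))
  grids[[bn]] <- cbind(band = bn, pb$correlations)
  scree <- data.frame(component = seq_along(ve), variance_explained = ve)
  write.csv(scree, sprintf("results/scree_%s.csv", bn), row.names = FALSE)
}
sel <- do.call(rbind, rows)
cat("\nelbow-selected connectivity patterns per band:\n")
print(sel, row.names = FALSE)
write.csv(sel, "results/selected_components.csv", row.names = FALSE)

grid <- do.call(rbind, grids)
write.csv(grid, "results/cognition_correlations.csv", row.names = FALSE)
top <- grid[which.max(abs(grid$rho)), ]
cat(sprintf("\nstrongest pattern-cognition link: %s component %d vs %s, rho = %.3f (p = %.3g)\n",
            top$band, top$component, top$test, top$rho, top$p_value))
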