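#!/usr/bin/env Rscript
# Simulate the study cohort: 43 PD patients, 90 AAL ROIs, six frequency
# bands, DBS ON/OFF PLI matrices with the planted effect structure the
# downstream analyses are designed to detect, and write it to disk in the
# plain-text cohort layout. Also emits the oddball paradigm event table.
suppressMessages(library(dbsconnect))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/cohort"
dir.create("results", showWarnings = FALSE)

paradigm <- generate_paradigm(seed = seed)
write.csv(paradigm, "results/paradigm.csv", row.names = FALSE)
cat(sprintf("paradigm: %d stimuli (%.0f%% targets), %.0f min\n",
            nrow(paradigm), 100 * mean(paradigm$type == "target"),
            nrow(paradigm) * 4.2 / 60))

spec <- cohort_spec(seed = seed)
cohort <- generate_fc_cohort(spec)
manifest <- write_cohort(cohort, out)
cat(sprintf("cohort: %d subjects x %d ROIs x %d bands -> %s\n",
            spec$n_subjects, spec$roi_count, length(spec$bands), manifest))
cat(sprintf("UPDRS_diff range: [%d, %d]; %d optimal responders (< %g)\n",
            min(cohort$metadata$updrs_diff), max(cohort$metadata$updrs_diff),
            sum(cohort$ground_truth$responder), spec$responder_threshold))
cat(sprintf("edge clipping after planting: %.2f%%\n",
            100 * cohort$clip_fraction))
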