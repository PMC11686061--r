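#!/usr/bin/env Rscript
# Responder classification: nested leave-one-out cross-validation with an
# inner threshold sweep over observed UPDRS_diff levels, 4-SD connectivity
# profile extraction from possibly-optimal responders, and a linear SVM on
# DBS OFF profile features. Reports PPV/NPV/sensitivity/specificity averaged
# over folds and repetitions, the modal response threshold, and the final
# connectivity profile.
suppressMessages(library(dbsconnect))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
reps <- if (length(args) > 1) as.integer(args[[2]]) else 3L
dir.create("results", showWarnings = FALSE)

cohort <- load_cohort("results/cohort/manifest.json")
report <- nested_loocv(cohort, repetitions = reps, seed = seed)
print(report)

prof <- report$final_profile
cat(sprintf("profile spans bands: %s\n",
            paste(unique(prof$band), collapse = ", ")))
write.csv(prof[setdiff(names(prof), "col")],
          "results/final_profile.csv", row.names = FALSE)
jsonlite::write_json(
  list(ppv = report$ppv, npv = report$npv,
       sensitivity = report$sensitivity, specificity = report$specificity,
       final_threshold = report$final_threshold,
       n_profile_edges = nrow(prof),
       n_unclassifiable = report$n_unclassifiable),
  "results/classification_report.json", auto_unbox = TRUE, digits = NA)
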