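#!/usr/bin/env Rscript
# Call tau positivity (SUVR > 1.23), compute per-ROI tau+ prevalence, and
# select search seeds (prevalence > 80%, per hemisphere). The off-target
# basal-ganglia ROIs are expected among the seeds: they carry elevated
# tracer signal and enter the search unchanged, serving as negative controls.

suppressPackageStartupMessages(library(ddis))

cohort <- load_cohort("results/cohort/subjects.tsv",
                      "results/cohort/nodes.tsv",
                      "results/cohort/edges.tsv",
                      "results/cohort/parcellation.tsv")
pos <- call_positivity(cohort$node_signal$tau_suvr, cutoff = 1.23)
prev <- compute_prevalence(pos, signal = "tau_suvr", cutoff = 1.23)
seeds <- select_seeds(prev, cohort$parcellation, threshold = 0.80)
write_prevalence_table(prev, cohort$parcellation, seeds,
                       "results/prevalence.tsv")

parc <- cohort$parcellation
cat("Seed ROIs (tau+ prevalence > 80%):", length(seeds$roi_ids), "\n")
print(data.frame(roi = parc$name[seeds$roi_ids],
                 hemisphere = parc$hemisphere[seeds$roi_ids],
                 off_target = parc$off_target[seeds$roi_ids],
                 prevalence = round(as.numeric(prev)[seeds$roi_ids], 3)))
cat("Top non-seed prevalence:",
    round(max(as.numeric(prev)[-seeds$roi_ids]), 3), "\n")
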