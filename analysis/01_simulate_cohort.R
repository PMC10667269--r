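#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 93 TSC infants sampled serially
# from enrollment to 104 weeks plus 58 single-sample controls; protein (340),
# metabolite (249), RNA (1000), miRNA (45) and SNP (86) panels with planted
# batch offsets, vigabatrin effects (up to 52-fold), developmental
# trajectories and three seizure-predictive analytes. Writes the per-type
# matrices, the sample metadata and the ground-truth ledger under
# results/cohort/.

suppressPackageStartupMessages(library(seizomics))
seed <- 20240101
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_config(), seed = seed)

for (type in names(cohort$matrices))
  write_analyte_matrix(cohort$matrices[[type]],
                       file.path(out, paste0(type, ".tsv")))
write_sample_metadata(cohort$meta, file.path(out, "metadata.tsv"))
write.table(cohort$truth, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- select_classifier_cohort(cohort$meta)
cat(sprintf("cohort: %d samples from %d subjects (%d TSC, %d control)\n",
            nrow(cohort$meta), length(unique(cohort$meta$subject_id)),
            sum(cohort$meta$group == "tsc"),
            sum(cohort$meta$group == "control")))
cat(sprintf("classifier-eligible subjects: %d (%d seizure / %d seizure-free)\n",
            nrow(sel), sum(sel$label == 1), sum(sel$label == 0)))
cat("written to ", out, "\n", sep = "")
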