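#!/usr/bin/env Rscript
# Stage 5 — exhaustive low-order classifier search on enrollment samples.
#
# Selects the classifier cohort (65 subjects, 54 seizure / 11 seizure-free),
# prefilters RNA on raw counts, pools features by univariate AUC (> 0.6, at
# most 30 per data type), enumerates every 1-3 variable logistic model and
# scores each by 100x stratified 2/3-1/3 Monte-Carlo cross-validation (mean
# test MCC, with MMCE/PPV/NPV). Writes pool.tsv and models.tsv under
# results/classifier/.

suppressPackageStartupMessages(library(seizomics))
seed <- 20240105
out <- "results/classifier"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata("results/cohort/metadata.tsv")
cohort <- select_classifier_cohort(meta)
cat(sprintf("cohort: %d subjects (%d/%d)\n", nrow(cohort),
            sum(cohort$label == 1), sum(cohort$label == 0)))

mats <- list(
  protein = read_analyte_matrix("results/cohort/protein.tsv", "protein",
                                "log2"),
  metabolite = read_analyte_matrix("results/cohort/metabolite.tsv",
                                   "metabolite", "log2"),
  mirna = read_analyte_matrix("results/cohort/mirna.tsv", "mirna", "log2"),
  snp = read_analyte_matrix("results/cohort/snp.tsv", "snp", "categorical"))
counts <- read_analyte_matrix("results/cohort/rna.tsv", "rna", "linear")
enroll_counts <- amx_update(counts,
                            unclass(counts)[, cohort$sample_id, drop = FALSE])
kept <- prefilter_rna(enroll_counts, cohort$label)
cat(sprintf("RNA prefilter: %d/%d genes retained\n", nrow(kept),
            nrow(counts)))
mats$rna <- amx_update(rna_log2cpm(counts),
                       unclass(rna_log2cpm(counts))[rownames(kept), ,
                                                    drop = FALSE])

cd <- assemble_classifier_data(mats, cohort)
pool <- build_feature_pool(cd$X, cd$feature_type, cd$labels,
                           auc_min = 0.6, per_type_cap = 30)
write.table(pool, file.path(out, "pool.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("feature pool: %d variables (%s)\n", nrow(pool),
            paste(sprintf("%s=%d", names(table(pool$data_type)),
                          table(pool$data_type)), collapse = ", ")))
cat(sprintf("model space: %d models\n", sum(choose(nrow(pool), 1:3))))

res <- run_search(cd$X, cd$labels, pool, max_order = 3, n_subsamples = 100,
                  seed = seed)
write.table(res, file.path(out, "models.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top 10 models by mean test MCC:\n")
print(head(res, 10), digits = 3)
cat("model table written to ", out, "\n", sep = "")
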