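#!/usr/bin/env Rscript
# Stage 6 — whole-experiment permutation significance.
#
# Permutes the outcome labels and repeats the entire experiment (feature
# pooling by AUC, exhaustive search, reduced 50x subsampling) to build the
# pooled null distribution of mean test MCC; every real model receives the
# fraction of null values at least as large, and the significance threshold
# is the 95th null percentile. Re-runs the real search at the stage-5
# settings, then writes models_with_p.tsv and permutation_null.tsv under
# results/classifier/.

suppressPackageStartupMessages(library(seizomics))
seed <- 20240105
out <- "results/classifier"
n_perm <- 30

meta <- read_sample_metadata("results/cohort/metadata.tsv")
cohort <- select_classifier_cohort(meta)
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
kept <- suppressWarnings(prefilter_rna(enroll_counts, cohort$label))
mats$rna <- amx_update(rna_log2cpm(counts),
                       unclass(rna_log2cpm(counts))[rownames(kept), ,
                                                    drop = FALSE])
cd <- assemble_classifier_data(mats, cohort)

pool <- build_feature_pool(cd$X, cd$feature_type, cd$labels,
                           auc_min = 0.6, per_type_cap = 30)
res <- run_search(cd$X, cd$labels, pool, max_order = 3, n_subsamples = 100,
                  seed = seed)
cat(sprintf("real search: %d models, best mean test MCC %.3f\n",
            nrow(res), res$mcc[1]))

pt <- permutation_test(cd$X, cd$feature_type, cd$labels, res,
                       n_perm = n_perm, perm_subsamples = 50,
                       auc_min = 0.6, per_type_cap = 30, max_order = 3,
                       seed = seed + 1)
write.table(pt, file.path(out, "models_with_p.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(null_mcc = attr(pt, "null_mcc")),
            file.path(out, "permutation_null.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("pooled null: %d permuted models; MCC significance threshold %.3f\n",
            attr(pt, "n_null"), attr(pt, "mcc_threshold")))
cat(sprintf("models significant at p < 0.05: %d\n",
            sum(pt$p_value < 0.05, na.rm = TRUE)))
cat(sprintf("best model: %s (MCC %.3f, p = %.4f)\n",
            pt$model[1], pt$mcc[1], pt$p_value[1]))
cat("permutation results written to ", out, "\n", sep = "")
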