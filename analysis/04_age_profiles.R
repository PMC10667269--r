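#!/usr/bin/env Rscript
# Stage 4 — developmental trajectory analysis.
#
# On batch/drug-corrected but age-uncorrected data: per-analyte Spearman
# correlation with age (BH-adjusted), the age-tertile Kruskal-Wallis screen,
# and complete-linkage hierarchical clustering of the tertile median Z-score
# profiles of the significant analytes (k = 6 protein, 6 metabolite, 8 RNA).
# Writes profile tables and cluster assignments under results/age_profiles/.

suppressPackageStartupMessages(library(seizomics))
out <- "results/age_profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata("results/cohort/metadata.tsv")
panels <- list(
  protein = list(read_analyte_matrix("results/cohort/protein.tsv",
                                     "protein", "log2"), k = 6),
  metabolite = list(zscore_unzscore_correct(
    read_analyte_matrix("results/cohort/metabolite.tsv", "metabolite",
                        "log2"), meta, "batch", "mean"), k = 6),
  rna = list(rna_log2cpm(read_analyte_matrix("results/cohort/rna.tsv",
                                             "rna", "linear")), k = 8))

truth <- read.table("results/cohort/ground_truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

for (type in names(panels)) {
  m <- filter_missingness(panels[[type]][[1]])
  sp <- spearman_age_association(m, meta)
  kw <- kw_age_test(m, meta)
  write.table(merge(sp, kw, by = "analyte_id", suffixes = c("_rho", "_kw")),
              file.path(out, paste0(type, "_age_association.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d/%d (%.0f%%) age-associated (KW tertile FDR < 0.05); %d by Spearman\n",
              type, sum(kw$p_adj < 0.05), nrow(m),
              100 * mean(kw$p_adj < 0.05), sum(sp$p_adj < 0.05)))
  sig <- kw$analyte_id[kw$p_adj < 0.05]
  if (length(sig) < panels[[type]]$k) next
  msig <- amx_update(m, unclass(m)[sig, , drop = FALSE])
  cl <- cluster_age_trajectories(msig, meta, k = panels[[type]]$k)
  cl$archetype <- truth$archetype[match(cl$analyte_id, truth$analyte_id)]
  write.table(cl, file.path(out, paste0(type, "_clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  %d clusters over %d analytes; cluster sizes: %s\n",
              panels[[type]]$k, nrow(cl),
              paste(table(cl$cluster), collapse = ", ")))
}
cat("age-profile tables written to ", out, "\n", sep = "")
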