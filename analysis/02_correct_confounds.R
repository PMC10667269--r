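#!/usr/bin/env Rscript
# Stage 2 — confound correction, in the fixed order batch -> drug -> age.
#
# Metabolites: Z/un-Z batch correction, then Wilcoxon+BH selection of
# vigabatrin-affected metabolites (>40-week samples) and Z/un-Z correction of
# those only. All types: age correction by the two independent routes whose
# outputs downstream stages intersect — the random-intercept mixed model
# (value ~ age + (1|subject)) and the age-tertile Z/un-Z method. Writes both
# corrected sets under results/corrected/.

suppressPackageStartupMessages(library(seizomics))
indir <- "results/cohort"
out <- "results/corrected"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata(file.path(indir, "metadata.tsv"))
types <- c(protein = "log2", metabolite = "log2", mirna = "log2")
mats <- lapply(names(types), function(t)
  read_analyte_matrix(file.path(indir, paste0(t, ".tsv")), t, types[[t]]))
names(mats) <- names(types)
mats$rna <- rna_log2cpm(
  read_analyte_matrix(file.path(indir, "rna.tsv"), "rna", "linear"))

# batch and drug effects concern the metabolite panel
mats$metabolite <- zscore_unzscore_correct(mats$metabolite, meta,
                                           grouping = "batch",
                                           center_stat = "mean")
vgb_hits <- select_vgb_affected(mats$metabolite, meta)
cat(sprintf("vigabatrin-affected metabolites (FDR < 0.05): %d\n",
            length(vgb_hits)))
affected <- mats$metabolite[rownames(mats$metabolite) %in% vgb_hits, ,
                            drop = FALSE]
affected <- amx_update(mats$metabolite, affected)
corrected_sub <- zscore_unzscore_correct(affected, meta, grouping = "vgb",
                                         center_stat = "mean")
full <- unclass(mats$metabolite)
full[rownames(corrected_sub), ] <- unclass(corrected_sub)
mats$metabolite <- amx_update(mats$metabolite, full)

for (type in names(mats)) {
  m <- filter_missingness(mats[[type]])
  fit <- fit_lmm_age_model(m, meta)
  cat(sprintf("%s: %d/%d analytes kept, %d mixed models converged\n",
              type, nrow(m), nrow(mats[[type]]), sum(fit$converged)))
  write_analyte_matrix(apply_lmm_correction(m, meta, fit),
                       file.path(out, paste0(type, "_lmm.tsv")))
  write_analyte_matrix(age_tertile_correct(m, meta),
                       file.path(out, paste0(type, "_ztertile.tsv")))
}
cat("corrected matrices written to ", out, "\n", sep = "")
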