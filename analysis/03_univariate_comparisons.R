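#!/usr/bin/env Rscript
# Stage 3 — clinical comparisons with the dual-correction intersection rule.
#
# Runs the group comparisons on both corrected data sets (mixed-model route
# and age-tertile route) and reports only analytes significant under both
# (FDR < 0.05, median fold change > 1.5). Comparison I contrasts control
# vs untreated pre-seizure TSC samples; Vb contrasts control / TSC
# never-epilepsy / TSC epilepsy on enrollment samples, under stringent and
# relaxed group definitions. Writes per-comparison hit tables under
# results/univariate/.

suppressPackageStartupMessages(library(seizomics))
out <- "results/univariate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata("results/cohort/metadata.tsv")
types <- c("protein", "metabolite", "rna", "mirna")
read_set <- function(route) {
  m <- lapply(types, function(t)
    read_analyte_matrix(sprintf("results/corrected/%s_%s.tsv", t, route),
                        t, "log2"))
  names(m) <- types
  m
}
lmm <- read_set("lmm")
zt <- read_set("ztertile")

runs <- list(list("I", "strict"), list("Vb", "strict"), list("Vb", "relaxed"))
for (r in runs) {
  comparison <- r[[1]]; stringency <- r[[2]]
  res <- run_comparison(comparison, lmm, zt, meta, stringency = stringency)
  label <- paste0(comparison, "_", stringency)
  write.table(res, file.path(out, paste0(label, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- attr(res, "groups")
  cat(sprintf("comparison %-10s groups: %s -> %d dual-route hits\n", label,
              paste(sprintf("%s=%d", names(g), lengths(g)), collapse = ", "),
              nrow(res)))
  if (nrow(res))
    cat("  hits: ", paste(res$analyte_id, collapse = ", "), "\n", sep = "")
}
cat("univariate tables written to ", out, "\n", sep = "")
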