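# shared fixtures and independent oracles used across the suite

# minimal metadata table for n samples (single-type tests that only need
# ages/subjects/batches/exposure flags)
meta_template <- function(n, subject_id = sprintf("p%03d", seq_len(n)),
                          age_weeks = rep(50, n), batch = rep(1L, n),
                          vgb = rep(FALSE, n), group = rep("tsc", n),
                          seizure_history = rep(FALSE, n),
                          timepoint_label = rep("x", n)) {
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             subject_id = subject_id, age_weeks = age_weeks, batch = batch,
             vgb = vgb, group = group, seizure_history = seizure_history,
             seizure_before_draw = FALSE, abnormal_eeg_at_draw = FALSE,
             seizure_at_draw = FALSE, drug_resistant_24m = NA,
             presymptomatic_vgb = FALSE, timepoint_label = timepoint_label,
             stringsAsFactors = FALSE)
}

# cohort configuration with no planted effects of any kind
null_config <- function(n_analytes = c(protein = 50, metabolite = 0, rna = 0,
                                       mirna = 0, snp = 0), ...) {
  cohort_config(n_analytes = n_analytes,
                vgb_effect_spec = data.frame(analyte = character(),
                                             fold = numeric()),
                group_effect_spec = data.frame(analyte = character(),
                                               log2_step = numeric()),
                planted_predictors = data.frame(analyte = character(),
                                                auc = numeric()),
                ...)
}

# brute-force Benjamini-Hochberg step-up: adj(i) = min_{k >= i} m p(k) / k
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force AUC by pair counting: U / (n1 n0) with half-credit for ties
auc_brute <- function(values, labels) {
  x <- values[labels == 1]
  y <- values[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# phi coefficient of the binary prediction/truth vectors of a confusion table
phi_from_counts <- function(tp, tn, fp, fn) {
  pred <- rep(c(1, 1, 0, 0), c(tp, fp, tn, fn))
  truth <- rep(c(1, 0, 0, 1), c(tp, fp, tn, fn))
  if (length(pred) < 2 || stats::sd(pred) == 0 || stats::sd(truth) == 0)
    return(NA_real_)
  stats::cor(pred, truth)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# mean silhouette of a 2-level grouping in a point cloud (rows = points)
silhouette_mean <- function(points, grouping) {
  d <- as.matrix(stats::dist(points))
  g <- as.integer(factor(grouping))
  s <- vapply(seq_len(nrow(points)), function(i) {
    own <- g == g[i]
    a <- mean(d[i, own & seq_along(g) != i])
    b <- min(vapply(setdiff(unique(g), g[i]),
                    function(k) mean(d[i, g == k]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# metadata for a longitudinal design: n_subjects x timepoints, random ages
lmm_design <- function(n_subjects, n_time = 3, seed = 1) {
  set.seed(seed)
  ages <- as.numeric(replicate(n_subjects, sort(sample(0:104, n_time))))
  meta_template(n_subjects * n_time,
                subject_id = rep(sprintf("p%03d", seq_len(n_subjects)),
                                 each = n_time),
                age_weeks = ages)
}

# simulate one analyte over a design: slope * age + subject intercept + noise
lmm_values <- function(meta, slope, intercept_sd, resid_sd, base = 10,
                       seed = 1) {
  set.seed(seed + 1e6)
  subj <- factor(meta$subject_id)
  u <- stats::rnorm(nlevels(subj), 0, intercept_sd)
  base + slope * meta$age_weeks + u[as.integer(subj)] +
    stats::rnorm(nrow(meta), 0, resid_sd)
}

as_amx <- function(values_row, meta, data_type = "protein", scale = "log2",
                   id = "a1") {
  m <- matrix(values_row, nrow = 1,
              dimnames = list(id, meta$sample_id))
  analyte_matrix(m, data_type = data_type, scale = scale)
}
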