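#' Z-score / un-Z-score confound correction
#'
#' For each analyte, values are standardised within each confound group
#' (batch, vigabatrin exposure, or age tertile) and rescaled by the global
#' statistics of all samples computed before the correction: the group
#' distributions are equalised while the overall location and spread of the
#' analyte are preserved. Standard deviations use the population (denominator
#' n) convention, which makes the correction exactly idempotent. Missing
#' values are ignored in all statistics and stay masked. Analyte/group
#' combinations with fewer than two observed values or an SD below 1e-12 are
#' passed through unchanged (a message records them).
#'
#' @param matrix an [analyte_matrix()] on the log2 scale.
#' @param meta sample metadata covering every matrix column.
#' @param grouping `"batch"`, `"vgb"`, or `"age_tertile"`.
#' @param center_stat `"mean"` (batch/vgb default) or `"median"`.
#' @return The corrected `analyte_matrix`.
#' @export
zscore_unzscore_correct <- function(matrix, meta,
                                    grouping = c("batch", "vgb", "age_tertile"),
                                    center_stat = c("mean", "median")) {
  grouping <- match.arg(grouping)
  center_stat <- match.arg(center_stat)
  stopifnot(inherits(matrix, "analyte_matrix"))
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  g <- switch(grouping,
              batch = as.factor(meta$batch[idx]),
              vgb = factor(meta$vgb[idx], levels = c(FALSE, TRUE)),
              age_tertile = age_tertile(meta$age_weeks[idx]))
  g <- droplevels(g)
  cfun <- if (center_stat == "mean") function(v) mean(v) else function(v) stats::median(v)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

  v <- unclass(matrix)
  out <- v
  skipped <- 0L
  for (a in seq_len(nrow(v))) {
    row <- v[a, ]
    obs <- !is.na(row)
    if (sum(obs) < 2) next
    ref_center <- cfun(row[obs])
    ref_sd <- pop_sd(row[obs])
    if (ref_sd < 1e-12) next
    for (lev in levels(g)) {
      sel <- obs & g == lev
      n <- sum(sel)
      if (n == 0) next
      if (n < 2) { skipped <- skipped + 1L; next }
      gc <- cfun(row[sel]); gs <- pop_sd(row[sel])
      if (gs < 1e-12) { skipped <- skipped + 1L; next }
      out[a, sel] <- (row[sel] - gc) / gs * ref_sd + ref_center
    }
  }
  if (skipped > 0)
    message(skipped, " analyte/group combination(s) passed through unchanged ",
            "(constant or < 2 observed values)")
  amx_update(matrix, out)
}

#' Select vigabatrin-affected analytes
#'
#' Restricting to samples above an age cutoff (where developmental effects
#' are minimal), each analyte is tested between exposed and unexposed samples
#' with a two-sided Wilcoxon rank-sum test; analytes with Benjamini-Hochberg
#' adjusted p below `fdr` are returned. Only these analytes should then be
#' passed through [zscore_unzscore_correct()] with `grouping = "vgb"`.
#'
#' @param matrix a metabolite [analyte_matrix()] (log2 scale).
#' @param meta sample metadata.
#' @param min_age_weeks age cutoff, default 40 weeks.
#' @param fdr FDR threshold, default 0.05.
#' @return Character vector of selected analyte ids, with a `results`
#'   attribute (data.frame of per-analyte p and adjusted p).
#' @export
select_vgb_affected <- function(matrix, meta, min_age_weeks = 40, fdr = 0.05) {
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  keep <- meta$age_weeks[idx] > min_age_weeks
  exposed <- meta$vgb[idx]
  if (!any(keep & exposed) || !any(keep & !exposed))
    stop("one exposure group is empty above the age cutoff")
  v <- unclass(matrix)[, keep, drop = FALSE]
  expv <- exposed[keep]
  p <- apply(v, 1, function(row) {
    x <- row[expv & !is.na(row)]
    y <- row[!expv & !is.na(row)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  padj <- rep(NA_real_, length(p))
  padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  res <- data.frame(analyte_id = rownames(matrix), p = p, p_adj = padj,
                    stringsAsFactors = FALSE)
  sel <- res$analyte_id[!is.na(res$p_adj) & res$p_adj < fdr]
  attr(sel, "results") <- res
  sel
}

#' Age-tertile Z-score correction
#'
#' [zscore_unzscore_correct()] with `grouping = "age_tertile"`; the tertiles
#' are fixed at 0-10, 11-40 and >40 weeks. The default centre statistic is
#' the median for this path.
#'
#' @inheritParams zscore_unzscore_correct
#' @export
age_tertile_correct <- function(matrix, meta, center_stat = "median") {
  zscore_unzscore_correct(matrix, meta, grouping = "age_tertile",
                          center_stat = center_stat)
}

#' Fit per-analyte random-intercept age models
#'
#' For every analyte, fits `value ~ age_weeks + (1 | subject)` by REML: a
#' global intercept, a fixed slope per week of age, and a random intercept
#' per subject (shrunk toward zero for subjects with few samples). Analytes
#' whose residual after an ordinary least-squares fit is numerically zero are
#' solved exactly without the mixed model (slope = OLS slope, zero random
#' intercepts). Non-converging analytes are flagged and excluded from
#' correction.
#'
#' @param matrix an [analyte_matrix()] (log2 scale).
#' @param meta sample metadata.
#' @return An object of class `lmm_age_model`: a list with per-analyte
#'   `slope`, `intercept`, `sigma` (residual SD), `converged`, and a
#'   `ranef` matrix (analyte x subject random intercepts).
#' @export
fit_lmm_age_model <- function(matrix, meta) {
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  age <- meta$age_weeks[idx]
  subject <- factor(meta$subject_id[idx])
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  v <- unclass(matrix)
  k <- nrow(v)
  slope <- intercept <- sigma <- rep(NA_real_, k)
  converged <- rep(FALSE, k)
  ranef <- matrix(0, nrow = k, ncol = nlevels(subject),
                  dimnames = list(rownames(v), levels(subject)))
  for (a in seq_len(k)) {
    y <- v[a, ]
    obs <- !is.na(y)
    if (sum(obs) < 3) next
    dat <- data.frame(y = y[obs], age = age[obs], subject = subject[obs])
    ols <- stats::lm(y ~ age, data = dat)
    if (stats::sigma(ols) < 1e-10) {
      slope[a] <- unname(stats::coef(ols)[2])
      intercept[a] <- unname(stats::coef(ols)[1])
      sigma[a] <- 0
      converged[a] <- TRUE
      next
    }
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ age + (1 | subject), data = dat, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.rankZ = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    fe <- lme4::fixef(fit)
    slope[a] <- unname(fe[["age"]])
    intercept[a] <- unname(fe[["(Intercept)"]])
    sigma[a] <- stats::sigma(fit)
    re <- lme4::ranef(fit)$subject
    ranef[a, rownames(re)] <- re[["(Intercept)"]]
    converged[a] <- TRUE
  }
  structure(list(analyte_id = rownames(v), slope = slope,
                 intercept = intercept, sigma = sigma,
                 converged = converged, ranef = ranef),
            class = "lmm_age_model")
}

#' Apply the mixed-model age correction
#'
#' Subtracts the fitted fixed age contribution and the subject random
#' intercept from every observation: `corrected = value - age * slope -
#' b_subject`. The global intercept is deliberately retained, so corrected
#' values stay on the original scale. Analytes whose model did not converge
#' are dropped from the output.
#'
#' @param matrix the matrix the model was fitted on (or one with identical
#'   analytes/samples).
#' @param meta sample metadata.
#' @param model an `lmm_age_model` from [fit_lmm_age_model()].
#' @return The corrected `analyte_matrix` (converged analytes only).
#' @export
apply_lmm_correction <- function(matrix, meta, model) {
  stopifnot(inherits(model, "lmm_age_model"))
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  age <- meta$age_weeks[idx]
  subject <- meta$subject_id[idx]
  unknown <- setdiff(unique(subject), colnames(model$ranef))
  if (length(unknown))
    stop("sample(s) whose subject has no fitted intercept: ",
         paste(unknown, collapse = ", "))
  keep <- which(model$converged & rownames(matrix) %in% model$analyte_id)
  rows <- match(model$analyte_id, rownames(matrix))
  v <- unclass(matrix)
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(v),
                dimnames = list(model$analyte_id[keep], colnames(v)))
  for (j in seq_along(keep)) {
    a <- keep[j]
    out[j, ] <- v[rows[a], ] - age * model$slope[a] -
      model$ranef[a, subject]
  }
  analyte_matrix(out, data_type = amx_data_type(matrix),
                 scale = amx_scale(matrix))
}
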