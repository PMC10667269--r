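#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Type-specific missingness filter
#'
#' Retains analytes whose fraction of observed, non-zero values meets the
#' type-specific threshold: 0.5 for RNA, metabolites and miRNA; 0.7 for
#' protein groups. Zeros count as unseen even when not masked.
#'
#' @param matrix an [analyte_matrix()].
#' @return The filtered `analyte_matrix`.
#' @export
filter_missingness <- function(matrix) {
  if (nrow(matrix) == 0 || ncol(matrix) == 0) stop("empty matrix")
  thr <- switch(amx_data_type(matrix),
                protein = 0.7,
                rna = , metabolite = , mirna = 0.5,
                0.5)
  seen <- rowMeans(!is.na(unclass(matrix)) & unclass(matrix) != 0)
  keep <- seen >= thr
  amx_update(matrix, unclass(matrix)[keep, , drop = FALSE])
}

#' Median fold change between two groups
#'
#' On log2-scale data the fold is `2^(median(x) - median(y))`; on linear
#' scale it is `median(x)/median(y)`.
#'
#' @param x,y numeric value vectors (missing values dropped).
#' @param scale `"log2"` or `"linear"`.
#' @return A list with `fold` (> 0, or `NA` when undefined) and `direction`
#'   (`"up"` if fold > 1 else `"down"`).
#' @export
median_fold_change <- function(x, y, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("groups must be non-empty")
  if (scale == "log2") {
    fold <- 2^(stats::median(x) - stats::median(y))
  } else {
    my <- stats::median(y)
    if (my == 0) return(list(fold = NA_real_, direction = NA_character_))
    fold <- stats::median(x) / my
  }
  list(fold = fold, direction = if (fold > 1) "up" else "down")
}

#' Assumption-gated two-group test
#'
#' Tests t-test assumptions first: Shapiro-Wilk normality in each group and
#' an F-test of variance homogeneity, all at `alpha_gate`. If every gate
#' passes, a two-sided t-test is used; otherwise a two-sided Wilcoxon
#' rank-sum test. Groups with fewer than 3 values (the Shapiro-Wilk minimum)
#' force the Wilcoxon branch.
#'
#' @param x,y numeric value vectors (missing values dropped).
#' @param alpha_gate significance level of the assumption checks.
#' @return A list with `test` (`"t"` or `"wilcoxon"`), `p`, `n` (per-group
#'   counts), and the gate p-values.
#' @export
two_group_test <- function(x, y, alpha_gate = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  sw_x <- sw_y <- f_p <- NA_real_
  use_t <- FALSE
  if (length(x) >= 3 && length(y) >= 3 &&
      stats::sd(x) > 0 && stats::sd(y) > 0) {
    sw_x <- stats::shapiro.test(x)$p.value
    sw_y <- stats::shapiro.test(y)$p.value
    f_p <- stats::var.test(x, y)$p.value
    use_t <- sw_x > alpha_gate && sw_y > alpha_gate && f_p > alpha_gate
  }
  if (use_t) {
    p <- stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$p.value
  }
  if (is.na(p)) p <- 1  # constant data in both groups
  list(test = if (use_t) "t" else "wilcoxon", p = p,
       n = c(length(x), length(y)),
       shapiro_p = c(sw_x, sw_y), f_p = f_p)
}

# Dunn's post-hoc pairwise z-tests on pooled ranks with tie correction
dunn_test <- function(groups) {
  k <- length(groups)
  all_v <- unlist(groups, use.names = FALSE)
  n <- length(all_v)
  r <- rank(all_v)
  sizes <- lengths(groups)
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  rbar <- vapply(seq_len(k), function(i) mean(r[starts[i]:stops[i]]), 0)
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  out <- data.frame(g1 = pairs[1, ], g2 = pairs[2, ], z = NA_real_,
                    p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
               (1 / sizes[i1] + 1 / sizes[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    out$z[j] <- z
    out$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Three-group Kruskal-Wallis test with Dunn post-hoc
#'
#' Kruskal-Wallis rank-sum test across the groups; when significant at
#' `alpha`, Dunn's two-sided pairwise z-tests (tie-corrected pooled ranks)
#' are run with Benjamini-Hochberg adjustment across the pairs. A pairwise
#' contrast is flagged significant when its adjusted p < `alpha` and its
#' median fold change exceeds `fold_min`.
#'
#' @param groups list of 3 numeric vectors (missing values dropped).
#' @param scale `"log2"` or `"linear"`, for the pairwise fold changes.
#' @param alpha significance level.
#' @param fold_min pairwise fold-change requirement.
#' @return A list with `kw_p`, `kw_stat`, and `pairs` (data.frame of Dunn z,
#'   p, adjusted p, fold, and significance flag; `NULL` when the omnibus
#'   test is not significant or degenerate).
#' @export
three_group_test <- function(groups, scale = "log2", alpha = 0.05,
                             fold_min = 1.5) {
  stopifnot(length(groups) == 3)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  if (length(unique(all_v)) == 1)
    return(list(kw_p = 1, kw_stat = 0, pairs = NULL))
  kw <- stats::kruskal.test(groups)
  if (is.na(kw$p.value))
    return(list(kw_p = 1, kw_stat = 0, pairs = NULL))
  pairs <- NULL
  if (kw$p.value < alpha) {
    pairs <- dunn_test(groups)
    pairs$fold <- vapply(seq_len(nrow(pairs)), function(j) {
      f <- median_fold_change(groups[[pairs$g1[j]]], groups[[pairs$g2[j]]],
                              scale = scale)$fold
      if (is.na(f)) 1 else f
    }, 0)
    pairs$significant <- pairs$p_adj < alpha &
      pmax(pairs$fold, 1 / pairs$fold) > fold_min
  }
  list(kw_p = kw$p.value, kw_stat = unname(kw$statistic), pairs = pairs)
}

#' Intersect significant sets from the two age-correction routes
#'
#' The conservative dual-method rule: an analyte is reported only when it is
#' significant (FDR < `fdr` and fold > `fold_min`) under both the
#' mixed-model and the age-tertile corrections.
#'
#' @param results_lmm,results_ztertile data.frames with columns `analyte_id`,
#'   `p_adj`, `fold` covering the same analytes.
#' @param fdr,fold_min significance thresholds.
#' @return The subset of `results_lmm` passing under both methods, with the
#'   tertile-route statistics joined as `p_adj_ztertile`, `fold_ztertile`.
#' @export
dual_method_intersect <- function(results_lmm, results_ztertile,
                                  fdr = 0.05, fold_min = 1.5) {
  if (!setequal(results_lmm$analyte_id, results_ztertile$analyte_id))
    stop("the two result sets cover different analytes")
  sig <- function(df) {
    f <- pmax(df$fold, 1 / df$fold)
    !is.na(df$p_adj) & df$p_adj < fdr & !is.na(f) & f > fold_min
  }
  m <- match(results_lmm$analyte_id, results_ztertile$analyte_id)
  keep <- sig(results_lmm) & sig(results_ztertile)[m]
  out <- results_lmm[keep, , drop = FALSE]
  out$p_adj_ztertile <- results_ztertile$p_adj[m][keep]
  out$fold_ztertile <- results_ztertile$fold[m][keep]
  out
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of overlap between a hit set and each
#' named pathway set, within a stated analyte universe, with
#' Benjamini-Hochberg adjustment across pathways.
#'
#' @param hit_set character vector of hit analyte ids (subset of universe).
#' @param pathway_sets named list of character vectors.
#' @param universe character vector of all tested analyte ids.
#' @return data.frame with per-pathway overlap, p, and adjusted p.
#' @export
hypergeom_enrich <- function(hit_set, pathway_sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(hit_set %in% universe)) stop("hit_set must be within the universe")
  hit_set <- unique(hit_set)
  universe <- unique(universe)
  res <- lapply(names(pathway_sets), function(nm) {
    pw <- intersect(pathway_sets[[nm]], universe)
    ov <- length(intersect(hit_set, pw))
    # P(X >= ov), X ~ Hypergeom(|pw| white, |U|-|pw| black, |hits| drawn)
    p <- stats::phyper(ov - 1, length(pw), length(universe) - length(pw),
                       length(hit_set), lower.tail = FALSE)
    data.frame(pathway = nm, pathway_size = length(pw), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Sample-group assignments for the clinical comparisons
#'
#' Builds the group memberships for the named comparison:
#' \describe{
#'   \item{I}{control samples vs TSC samples drawn before any treatment or
#'     seizure (abnormal EEG allowed), any age.}
#'   \item{II}{samples drawn at seizure occurrence vs samples from subjects
#'     who never had seizures.}
#'   \item{III}{TSC samples at abnormal-EEG detection (no seizure) vs TSC
#'     samples with normal EEG and no seizure.}
#'   \item{IV}{24-month TSC samples: drug-resistant epilepsy vs seizure-free
#'     or drug-controlled.}
#'   \item{Va}{24-month TSC samples in three groups: seizure history /
#'     no history / no history with presymptomatic vigabatrin.}
#'   \item{Vb}{enrollment samples in three groups: age-comparable controls
#'     (age <= 17 weeks) / TSC never-epilepsy / TSC epilepsy. Stringent
#'     conditions drop presymptomatically treated subjects from group 2 and
#'     abnormal-EEG-at-enrollment subjects from groups 2 and 3; relaxed
#'     conditions keep both.}
#' }
#'
#' @param meta sample metadata.
#' @param comparison one of `"I"`, `"II"`, `"III"`, `"IV"`, `"Va"`, `"Vb"`.
#' @param stringency `"strict"` or `"relaxed"` (comparison Vb only).
#' @return Named list of sample-id vectors, one per group.
#' @export
comparison_groups <- function(meta,
                              comparison = c("I", "II", "III", "IV", "Va", "Vb"),
                              stringency = c("strict", "relaxed")) {
  comparison <- match.arg(comparison)
  stringency <- match.arg(stringency)
  m <- meta
  tsc <- m$group == "tsc"
  groups <- switch(comparison,
    I = list(
      control = m$sample_id[m$group == "control"],
      tsc = m$sample_id[tsc & !m$vgb & !m$seizure_before_draw]),
    II = list(
      at_seizure = m$sample_id[tsc & m$seizure_at_draw],
      seizure_free = m$sample_id[tsc & !m$seizure_history]),
    III = list(
      abnormal_eeg = m$sample_id[tsc & m$abnormal_eeg_at_draw &
                                   !m$seizure_at_draw],
      normal_eeg = m$sample_id[tsc & !m$abnormal_eeg_at_draw &
                                 !m$seizure_at_draw]),
    IV = list(
      drug_resistant = m$sample_id[tsc & m$timepoint_label == "24m" &
                                     !is.na(m$drug_resistant_24m) &
                                     m$drug_resistant_24m],
      controlled = m$sample_id[tsc & m$timepoint_label == "24m" &
                                 !is.na(m$drug_resistant_24m) &
                                 !m$drug_resistant_24m]),
    Va = list(
      seizure = m$sample_id[tsc & m$timepoint_label == "24m" &
                              m$seizure_history],
      seizure_free = m$sample_id[tsc & m$timepoint_label == "24m" &
                                   !m$seizure_history &
                                   !m$presymptomatic_vgb],
      seizure_free_presym = m$sample_id[tsc & m$timepoint_label == "24m" &
                                          !m$seizure_history &
                                          m$presymptomatic_vgb]),
    Vb = {
      enr <- m$timepoint_label == "enrollment"
      g2 <- tsc & enr & !m$seizure_history
      g3 <- tsc & enr & m$seizure_history
      if (stringency == "strict") {
        g2 <- g2 & !m$presymptomatic_vgb & !m$abnormal_eeg_at_draw
        g3 <- g3 & !(m$abnormal_eeg_at_draw & !m$seizure_at_draw)
      }
      g3 <- g3 & !m$seizure_at_draw  # entry-seizure subjects never comparable
      list(control = m$sample_id[m$group == "control" & m$age_weeks <= 17],
           tsc_no_epilepsy = m$sample_id[g2],
           tsc_epilepsy = m$sample_id[g3])
    })
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty))
    stop("comparison ", comparison, ": empty group(s) after selection: ",
         paste(empty, collapse = ", "))
  groups
}

# per-analyte two- or three-group testing over one corrected matrix
test_matrix_groups <- function(matrix, groups, fold_min = 1.5) {
  scale <- if (amx_scale(matrix) == "log2") "log2" else "linear"
  v <- unclass(matrix)
  res <- lapply(rownames(v), function(a) {
    vals <- lapply(groups, function(ids) {
      x <- v[a, intersect(ids, colnames(v))]
      x[!is.na(x)]
    })
    if (any(lengths(vals) < 2))
      return(data.frame(analyte_id = a, test = NA_character_, p = NA_real_,
                        fold = NA_real_, stringsAsFactors = FALSE))
    if (length(vals) == 2) {
      tt <- two_group_test(vals[[1]], vals[[2]])
      fc <- median_fold_change(vals[[1]], vals[[2]], scale = scale)$fold
      data.frame(analyte_id = a, test = tt$test, p = tt$p, fold = fc,
                 stringsAsFactors = FALSE)
    } else {
      kw <- three_group_test(vals, scale = scale, fold_min = fold_min)
      # fold reported against the first (reference) group, largest contrast
      f12 <- median_fold_change(vals[[2]], vals[[1]], scale = scale)$fold
      f13 <- median_fold_change(vals[[3]], vals[[1]], scale = scale)$fold
      fc <- if (max(f12, 1 / f12) >= max(f13, 1 / f13)) f12 else f13
      data.frame(analyte_id = a, test = "kruskal_wallis", p = kw$kw_p,
                 fold = fc, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}

#' Run a clinical comparison under both age-correction routes
#'
#' Assembles the group memberships for the named comparison, tests every
#' analyte in each corrected matrix (two-group gate or Kruskal-Wallis as the
#' group count dictates, BH adjustment across analytes within each data type
#' and route), and applies the conservative dual-route intersection.
#'
#' @param comparison comparison label, see [comparison_groups()].
#' @param matrices_lmm,matrices_ztertile named lists of corrected
#'   [analyte_matrix()] objects (same types and analytes in both).
#' @param meta sample metadata.
#' @param stringency Vb stringency.
#' @param fdr,fold_min significance thresholds.
#' @return data.frame of analytes significant under both routes, with per-route
#'   statistics; a `per_route` attribute carries the full per-route tables.
#' @export
run_comparison <- function(comparison, matrices_lmm, matrices_ztertile, meta,
                           stringency = "strict", fdr = 0.05, fold_min = 1.5) {
  groups <- comparison_groups(meta, comparison, stringency)
  all_lmm <- list(); all_zt <- list(); hits <- list()
  for (type in names(matrices_lmm)) {
    r1 <- test_matrix_groups(matrices_lmm[[type]], groups, fold_min)
    r2 <- test_matrix_groups(matrices_ztertile[[type]], groups, fold_min)
    r1$data_type <- type; r2$data_type <- type
    all_lmm[[type]] <- r1; all_zt[[type]] <- r2
    ok <- stats::complete.cases(r1[c("p_adj", "fold")]) &
      stats::complete.cases(r2[c("p_adj", "fold")])
    hit <- dual_method_intersect(r1[ok, , drop = FALSE],
                                 r2[ok, , drop = FALSE],
                                 fdr = fdr, fold_min = fold_min)
    if (nrow(hit)) hits[[type]] <- hit
  }
  out <- if (length(hits)) do.call(rbind, c(hits, list(make.row.names = FALSE)))
  else all_lmm[[1]][0, , drop = FALSE]
  attr(out, "per_route") <- list(lmm = do.call(rbind, all_lmm),
                                 ztertile = do.call(rbind, all_zt))
  attr(out, "groups") <- groups
  out
}
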