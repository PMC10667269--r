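#' Spearman association of each analyte with age
#'
#' Two-sided Spearman rank correlation of every analyte with postnatal age,
#' Benjamini-Hochberg adjusted across analytes. Meant to run on matrices
#' corrected for technical confounds but not for age.
#'
#' @param matrix an [analyte_matrix()].
#' @param meta sample metadata.
#' @return data.frame with `analyte_id`, `rho`, `p`, `p_adj`; constant
#'   analytes are excluded (recorded in the `excluded` attribute).
#' @export
spearman_age_association <- function(matrix, meta) {
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  age <- meta$age_weeks[idx]
  v <- unclass(matrix)
  rho <- p <- rep(NA_real_, nrow(v))
  for (a in seq_len(nrow(v))) {
    y <- v[a, ]
    obs <- !is.na(y)
    if (sum(obs) < 4 || stats::sd(y[obs]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(y[obs], age[obs], method = "spearman", exact = FALSE))
    rho[a] <- unname(ct$estimate)
    p[a] <- ct$p.value
  }
  ok <- !is.na(p)
  out <- data.frame(analyte_id = rownames(v)[ok], rho = rho[ok], p = p[ok],
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "excluded") <- rownames(v)[!ok]
  out
}

#' Kruskal-Wallis age-tertile association per analyte
#'
#' Tests each analyte across the three fixed age tertiles and adjusts across
#' analytes; the significant set feeds the trajectory clustering.
#'
#' @param matrix an [analyte_matrix()].
#' @param meta sample metadata.
#' @return data.frame with `analyte_id`, `p`, `p_adj`.
#' @export
kw_age_test <- function(matrix, meta) {
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  tert <- age_tertile(meta$age_weeks[idx])
  v <- unclass(matrix)
  p <- apply(v, 1, function(y) {
    obs <- !is.na(y)
    if (length(unique(y[obs])) < 2) return(NA_real_)
    if (any(table(tert[obs]) < 2)) return(NA_real_)
    stats::kruskal.test(y[obs], tert[obs])$p.value
  })
  ok <- !is.na(p)
  out <- data.frame(analyte_id = rownames(v)[ok], p = p[ok],
                    stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Cluster developmental trajectories
#'
#' Each analyte is Z-scored across its own samples, collapsed to its three
#' age-tertile medians, and the analyte x 3 profile matrix is clustered by
#' complete-linkage hierarchical clustering on Euclidean distances, cut at
#' `k` clusters. Analytes are sorted by id before clustering so the result
#' does not depend on input order.
#'
#' @param matrix an [analyte_matrix()]; typically restricted to analytes
#'   significant in [kw_age_test()].
#' @param meta sample metadata.
#' @param k number of clusters.
#' @return data.frame with `analyte_id`, the three tertile median Z-scores,
#'   and `cluster`; the dendrogram is attached as attribute `hclust`.
#' @export
cluster_age_trajectories <- function(matrix, meta, k) {
  if (k > nrow(matrix)) stop("k exceeds the number of analytes")
  idx <- match(colnames(matrix), meta$sample_id)
  if (any(is.na(idx))) stop("matrix columns missing from metadata")
  tert <- age_tertile(meta$age_weeks[idx])
  v <- unclass(matrix)[order(rownames(matrix)), , drop = FALSE]
  prof <- t(apply(v, 1, function(y) {
    z <- (y - mean(y, na.rm = TRUE)) / stats::sd(y, na.rm = TRUE)
    vapply(levels(tert), function(lv)
      stats::median(z[tert == lv], na.rm = TRUE), 0)
  }))
  colnames(prof) <- levels(tert)
  if (any(!is.finite(prof)))
    stop("tertile median undefined for some analyte (constant or empty tertile)")
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  out <- data.frame(analyte_id = rownames(prof), prof, cluster = unname(cl),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "hclust") <- hc
  out
}
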