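#' Deterministic child seeds
#'
#' Hashes a master seed with stream indices into a new seed below 2^31, so
#' every stochastic stage draws from its own reproducible stream.
#'
#' @param seed master integer seed.
#' @param ... integer stream indices.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  h <- 0
  for (v in c(seed, ...)) h <- (h * 7919 + (v %% 2147483629) + 1) %% 2147483629
  as.integer(h)
}

#' RNA prefilter for the classifier stage
#'
#' Two-step gene filter on raw counts: (1) more than `min_reads` reads in at
#' least `min_frac` of samples; (2) at least a `fold_min` median change in
#' counts-per-million between the two outcome classes (a zero median in one
#' class passes when the other is non-zero).
#'
#' @param counts an RNA count [analyte_matrix()] (`scale = "linear"`).
#' @param labels 0/1 outcome per sample (aligned with columns).
#' @param min_reads,min_frac,fold_min filter parameters.
#' @return The filtered count matrix (warning when nothing passes).
#' @export
prefilter_rna <- function(counts, labels, min_reads = 3, min_frac = 0.75,
                          fold_min = 2) {
  if (is.null(labels) || length(labels) != ncol(counts))
    stop("labels must be given for every sample")
  v <- unclass(counts)
  pass1 <- rowMeans(v > min_reads, na.rm = TRUE) >= min_frac
  lib <- colSums(v, na.rm = TRUE)
  cpm <- sweep(v, 2, pmax(lib, 1), "/") * 1e6
  m1 <- apply(cpm[, labels == 1, drop = FALSE], 1, stats::median, na.rm = TRUE)
  m0 <- apply(cpm[, labels == 0, drop = FALSE], 1, stats::median, na.rm = TRUE)
  fold_ok <- ifelse(m1 == 0 & m0 == 0, FALSE,
                    ifelse(m1 == 0 | m0 == 0, TRUE,
                           pmax(m1 / m0, m0 / m1) >= fold_min))
  keep <- pass1 & fold_ok
  if (!any(keep)) warning("no genes pass the RNA prefilter")
  amx_update(counts, v[keep, , drop = FALSE])
}

#' Rank-based univariate AUC
#'
#' The Mann-Whitney formulation with midrank tie handling: the probability
#' that a random positive sample scores above a random negative one (ties
#' counting one half).
#'
#' @param values numeric scores (missing values dropped pairwise with labels).
#' @param labels 0/1 class labels.
#' @return The AUC in \[0, 1\].
#' @export
compute_auc <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble the classifier feature table
#'
#' Extracts the enrollment-sample columns of every analyte matrix for the
#' selected cohort and stacks them into one sample x feature matrix with a
#' per-feature data-type map.
#'
#' @param matrices named list of [analyte_matrix()] objects.
#' @param cohort output of [select_classifier_cohort()].
#' @return A list with `X` (samples x features), `feature_type` (named
#'   character vector), and `labels` (0/1 per cohort subject).
#' @export
assemble_classifier_data <- function(matrices, cohort) {
  parts <- lapply(names(matrices), function(type) {
    m <- matrices[[type]]
    missing_s <- setdiff(cohort$sample_id, colnames(m))
    if (length(missing_s))
      stop("matrix '", type, "' lacks cohort samples: ",
           paste(utils::head(missing_s, 3), collapse = ", "))
    t(unclass(m)[, cohort$sample_id, drop = FALSE])
  })
  X <- do.call(cbind, parts)
  rownames(X) <- cohort$sample_id
  feature_type <- rep(names(matrices),
                      vapply(matrices, nrow, 0L))
  names(feature_type) <- colnames(X)
  list(X = X, feature_type = feature_type,
       labels = cohort$label)
}

#' Select the classifier feature pool by univariate AUC
#'
#' Constant features are removed; every remaining feature is scored by its
#' oriented AUC (`max(auc, 1 - auc)`); per data type, the top `per_type_cap`
#' features with oriented AUC above `auc_min` are kept (AUC ties broken by
#' feature id); the pool is their union.
#'
#' @param X sample x feature matrix.
#' @param feature_type named character vector mapping features to data types.
#' @param labels 0/1 outcome per sample.
#' @param auc_min oriented-AUC inclusion threshold (default 0.6).
#' @param per_type_cap per-type cap (default 30).
#' @param min_obs_frac features observed in fewer than this fraction of
#'   samples are ineligible (default 0.5), extending the constant-feature
#'   exclusion to near-unobserved features whose AUC would rest on a handful
#'   of cases.
#' @return data.frame `feature`, `data_type`, `auc`, `oriented_auc`, ordered
#'   by type then descending oriented AUC.
#' @export
build_feature_pool <- function(X, feature_type, labels, auc_min = 0.6,
                               per_type_cap = 30, min_obs_frac = 0.5) {
  stopifnot(ncol(X) == length(feature_type))
  const <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < max(2, min_obs_frac * nrow(X)) || stats::var(v) == 0
  })
  auc <- rep(NA_real_, ncol(X))
  for (j in which(!const))
    auc[j] <- tryCatch(compute_auc(X[, j], labels),
                       error = function(e) NA_real_)  # a class fully missing
  oa <- pmax(auc, 1 - auc)
  keep <- list()
  for (type in unique(feature_type)) {
    j <- which(feature_type == type & !const & !is.na(oa) & oa > auc_min)
    if (!length(j)) next
    ord <- j[order(-oa[j], colnames(X)[j])]
    keep[[type]] <- utils::head(ord, per_type_cap)
  }
  sel <- unlist(keep, use.names = FALSE)
  if (!length(sel))
    stop("empty feature pool: consider relaxing auc_min (", auc_min, ")")
  data.frame(feature = colnames(X)[sel],
             data_type = unname(feature_type[sel]),
             auc = auc[sel], oriented_auc = oa[sel],
             stringsAsFactors = FALSE)
}

#' Enumerate all variable subsets of size 1..max_order
#'
#' @param k pool size (or a pool data.frame from [build_feature_pool()]).
#' @param max_order largest model size (default 3).
#' @return List of integer index vectors, each subset exactly once, sizes
#'   ascending and lexicographic within size. Total length
#'   `sum(choose(k, 1:max_order))`.
#' @export
enumerate_models <- function(k, max_order = 3) {
  if (is.data.frame(k)) k <- nrow(k)
  if (max_order < 1) stop("max_order must be >= 1")
  out <- list()
  for (j in seq_len(min(max_order, k))) {
    cmb <- utils::combn(k, j)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging from -1
#' (complete disagreement) through 0 (no correlation) to 1 (complete
#' agreement); any zero factor in the denominator yields 0 by convention.
#'
#' @param tp,tn,fp,fn confusion counts (non-negative; not all zero).
#' @return The MCC.
#' @export
matthews_cc <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("at least one prediction is required")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Score one candidate model by Monte-Carlo cross-validation
#'
#' Complete cases for the variable set are split `train_frac` / rest with
#' class stratification, `n_subsamples` times; each split fits a ridge
#' logistic model (penalty `lambda` on slopes) on training data standardised
#' by training statistics, tunes the probability threshold maximising
#' training MCC, and scores the held-out set. Metrics are averaged over
#' splits; PPV/NPV over the splits where they are defined.
#'
#' @param variables feature names or column indices (1-3) into `X`.
#' @param X sample x feature matrix.
#' @param labels 0/1 outcome per sample.
#' @param n_subsamples number of random splits (default 100).
#' @param train_frac training fraction (default 2/3).
#' @param seed master seed.
#' @param lambda ridge penalty on slopes (default 1e-4).
#' @param standardize `"train"` (leak-free, default), `"global"`, or
#'   `"none"`.
#' @return A list with mean test `mcc`, `mmce`, `ppv`, `npv` (NA when never
#'   defined), `n_complete`, and the full-data `coefficients` and tuned
#'   `threshold`.
#' @export
evaluate_model <- function(variables, X, labels, n_subsamples = 100,
                           train_frac = 2 / 3, seed = 1, lambda = 1e-4,
                           standardize = c("train", "global", "none")) {
  standardize <- match.arg(standardize)
  if (is.character(variables)) variables <- match(variables, colnames(X))
  if (any(is.na(variables))) stop("unknown variable name")
  Xi <- prepare_X(X, standardize)
  res <- cpp_evaluate_models(Xi, as.integer(labels),
                             list(as.integer(variables)),
                             as.integer(n_subsamples), train_frac, lambda,
                             as.double(seed), standardize == "train")
  cc <- stats::complete.cases(Xi[, variables, drop = FALSE])
  Z <- scale(Xi[cc, variables, drop = FALSE])
  Z[, attr(Z, "scaled:scale") < 1e-12] <- 0
  beta <- cpp_fit_logistic(Z, as.integer(labels[cc]), lambda)
  prob <- 1 / (1 + exp(-(beta[1] + Z %*% beta[-1])))
  thr <- tune_threshold_r(as.numeric(prob), labels[cc])
  list(variables = colnames(X)[variables], mcc = unname(res[1, "mcc"]),
       mmce = unname(res[1, "mmce"]), ppv = unname(res[1, "ppv"]),
       npv = unname(res[1, "npv"]),
       n_complete = unname(res[1, "n_complete"]),
       coefficients = as.numeric(beta), threshold = thr)
}

prepare_X <- function(X, standardize) {
  if (standardize != "global") return(X)
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") < 1e-12 | is.na(attr(Z, "scaled:scale"))] <- 0
  Z
}

# training-MCC threshold grid used for the reported full-data threshold
tune_threshold_r <- function(prob, labels) {
  cand <- sort(unique(prob))
  cand <- c(cand, max(cand) + 1)
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    pred <- as.integer(prob >= t)
    m <- matthews_cc(sum(pred & labels), sum(!pred & !labels),
                     sum(pred & !labels), sum(!pred & labels))
    if (m > best + 1e-12) { best <- m; best_t <- t }
  }
  best_t
}

#' Exhaustive low-order logistic model search
#'
#' Evaluates every 1..`max_order` variable subset of the feature pool with
#' [evaluate_model()]'s Monte-Carlo scheme (in compiled code) and ranks
#' models by mean test MCC. Fully deterministic given `(X, pool, seed)`;
#' per-model child seeds make the ranking independent of enumeration order.
#'
#' @param X sample x feature matrix.
#' @param labels 0/1 outcome per sample.
#' @param pool a pool data.frame from [build_feature_pool()] (or character
#'   vector of feature names).
#' @param max_order largest model size (default 3).
#' @param n_subsamples splits per model (default 100).
#' @param train_frac training fraction (default 2/3).
#' @param seed master seed.
#' @param lambda ridge penalty (default 1e-4).
#' @param standardize see [evaluate_model()].
#' @param min_complete_frac models whose complete-case count falls below
#'   this fraction of the cohort are left unscored (`NA`, ranked last):
#'   a cross-validated metric over a handful of samples is noise, not
#'   evidence (default 0.5).
#' @return data.frame, one row per model, ranked by mean test MCC
#'   descending: `model` (feature names joined by " + "), `order`, `mcc`,
#'   `mmce`, `ppv`, `npv`, `n_complete`.
#' @export
run_search <- function(X, labels, pool, max_order = 3, n_subsamples = 100,
                       train_frac = 2 / 3, seed = 1, lambda = 1e-4,
                       standardize = c("train", "global", "none"),
                       min_complete_frac = 0.5) {
  standardize <- match.arg(standardize)
  feats <- if (is.data.frame(pool)) pool$feature else pool
  cols <- match(feats, colnames(X))
  if (any(is.na(cols))) stop("pool feature absent from X")
  models <- enumerate_models(length(feats), max_order)
  model_cols <- lapply(models, function(m) as.integer(cols[m]))
  Xi <- prepare_X(X, standardize)
  res <- cpp_evaluate_models(Xi, as.integer(labels), model_cols,
                             as.integer(n_subsamples), train_frac, lambda,
                             as.double(seed), standardize == "train")
  name <- vapply(models, function(m) paste(feats[m], collapse = " + "), "")
  out <- data.frame(model = name,
                    order = lengths(models),
                    mcc = res[, "mcc"], mmce = res[, "mmce"],
                    ppv = res[, "ppv"], npv = res[, "npv"],
                    n_complete = res[, "n_complete"],
                    stringsAsFactors = FALSE)
  thin <- out$n_complete < min_complete_frac * nrow(X)
  out$mcc[thin] <- NA_real_
  out <- out[order(-out$mcc, out$model, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Whole-experiment permutation significance test
#'
#' Repeats the entire experiment — feature-pool selection by AUC followed by
#' the exhaustive model search — on outcome-permuted labels, pooling the
#' mean test MCC of every permuted model into one null distribution. Each
#' real model's p-value is the fraction of pooled null MCCs at least as
#' large as its own mean test MCC; the significance threshold is the
#' `1 - alpha` quantile of the pooled null.
#'
#' Pooling every permuted model (`null_stat = "pooled"`, the default) mirrors
#' the study design but is anti-conservative for the top-ranked model, which
#' is a maximum over the whole search; `null_stat = "max"` instead compares
#' models against the per-permutation maximum MCCs (a max-T familywise
#' test), which is calibrated for the best model but coarse (granularity
#' `1/n_perm`).
#'
#' @param X sample x feature matrix (all candidate features, pre-pool).
#' @param feature_type named type map, as in [build_feature_pool()].
#' @param labels 0/1 outcome per sample.
#' @param real_results a ranked model table from [run_search()].
#' @param n_perm number of permutations (default 30).
#' @param perm_subsamples splits per permuted model (default 50).
#' @param auc_min,per_type_cap pool parameters (must match the real run).
#' @param max_order largest model size.
#' @param seed master seed.
#' @param alpha significance level (default 0.05).
#' @param lambda,train_frac,standardize forwarded to the search.
#' @param null_stat `"pooled"` (all permuted models, study convention) or
#'   `"max"` (per-permutation maxima, familywise).
#' @return `real_results` with a `p_value` column appended; attributes
#'   `null_mcc` (pooled null values), `mcc_threshold` (the `1 - alpha` null
#'   quantile) and `n_null`.
#' @export
permutation_test <- function(X, feature_type, labels, real_results,
                             n_perm = 30, perm_subsamples = 50,
                             auc_min = 0.6, per_type_cap = 30, max_order = 3,
                             seed = 1, alpha = 0.05, lambda = 1e-4,
                             train_frac = 2 / 3, standardize = "train",
                             null_stat = c("pooled", "max")) {
  null_stat <- match.arg(null_stat)
  if (n_perm < 2) stop("need at least 2 permutations")
  null_mcc <- list()
  for (i in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(seed, 1000003, i), sample(labels))
    pool_i <- tryCatch(
      build_feature_pool(X, feature_type, perm, auc_min = auc_min,
                         per_type_cap = per_type_cap),
      error = function(e) NULL)
    if (is.null(pool_i)) next  # empty pool: permutation contributes nothing
    res_i <- run_search(X, perm, pool_i, max_order = max_order,
                        n_subsamples = perm_subsamples,
                        train_frac = train_frac,
                        seed = derive_seed(seed, 2000003, i),
                        lambda = lambda, standardize = standardize)
    mccs <- res_i$mcc[!is.na(res_i$mcc)]
    null_mcc[[length(null_mcc) + 1]] <-
      if (null_stat == "max") max(mccs) else mccs
  }
  null_mcc <- unlist(null_mcc)
  if (!length(null_mcc)) stop("no permuted models could be evaluated")
  out <- real_results
  out$p_value <- vapply(out$mcc, function(m)
    if (is.na(m)) NA_real_ else mean(null_mcc >= m), 0)
  attr(out, "null_mcc") <- null_mcc
  attr(out, "mcc_threshold") <-
    unname(stats::quantile(null_mcc, 1 - alpha, names = FALSE))
  attr(out, "n_null") <- length(null_mcc)
  out
}
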