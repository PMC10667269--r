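test_that("the RNA prefilter applies both rules at their exact boundaries", {
  n <- 100
  labels <- rep(c(1, 0), c(80, 20))
  mk <- function(counts_row) {
    v <- rbind(counts_row, stable = rep(1000, n))
    rownames(v) <- c("g", "stable")
    colnames(v) <- sprintf("s%03d", 1:n)
    analyte_matrix(v, "rna", "linear")
  }
  # reads > 3 in 74% vs 75% of samples (fold rule satisfied by class split)
  row74 <- c(rep(100, 59), rep(10, 15), rep(0, 26))  # 74 samples > 3 reads
  row75 <- c(rep(100, 60), rep(10, 15), rep(0, 25))
  expect_false("g" %in%
                 rownames(suppressWarnings(prefilter_rna(mk(row74), labels))))
  expect_true("g" %in% rownames(prefilter_rna(mk(row75), labels)))
  # no gene passes: empty result with a warning
  allzero <- analyte_matrix(
    matrix(0, 2, n, dimnames = list(c("a", "b"), sprintf("s%03d", 1:n))),
    "rna", "linear")
  expect_warning(out <- prefilter_rna(allzero, labels), "no genes")
  expect_equal(nrow(out), 0)
  expect_error(prefilter_rna(mk(row75), NULL), "labels")
})

test_that("random count matrices match a brute-force filter recomputation", {
  set.seed(15)
  n <- 40
  labels <- rep(c(1, 0), c(30, 10))
  v <- matrix(rnbinom(200 * n, mu = 8, size = 0.5), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n)))
  m <- analyte_matrix(v, "rna", "linear")
  kept <- rownames(suppressWarnings(prefilter_rna(m, labels)))
  if (is.null(kept)) kept <- character(0)  # empty matrices drop dimnames
  cpm <- sweep(v, 2, pmax(colSums(v), 1), "/") * 1e6
  brute <- character()
  for (g in rownames(v)) {
    ok1 <- mean(v[g, ] > 3) >= 0.75
    m1 <- median(cpm[g, labels == 1]); m0 <- median(cpm[g, labels == 0])
    ok2 <- if (m1 == 0 && m0 == 0) FALSE
           else if (m1 == 0 || m0 == 0) TRUE
           else max(m1 / m0, m0 / m1) >= 2
    if (ok1 && ok2) brute <- c(brute, g)
  }
  expect_setequal(kept, brute)
})

test_that("rank AUC behaves at its extremes and matches pair counting", {
  expect_equal(compute_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(compute_auc(c(1, 2, 10, 11), c(1, 1, 0, 0)), 0)
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  # tie handling: half credit
  expect_equal(compute_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)),
               auc_brute(c(1, 2, 2, 3), c(0, 0, 1, 1)))
  set.seed(19)
  big <- compute_auc(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(big - 0.5), 0.03)
  # random small instances, heavy ties, against the pair-counting oracle
  for (i in 1:200) {
    n <- sample(4:8, 1)
    v <- sample(1:3, n, TRUE)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(compute_auc(v, l), auc_brute(v, l))
  }
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the feature pool honours threshold, cap and tie rules", {
  set.seed(25)
  n <- 60
  labels <- rep(c(1, 0), c(40, 20))
  k <- 50
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, sprintf("f%02d", 1:k)))
  X[labels == 1, ] <- X[labels == 1, ] + 1.2  # all informative
  ft <- setNames(rep("protein", k), colnames(X))
  pool <- build_feature_pool(X, ft, labels, auc_min = 0.6, per_type_cap = 30)
  expect_equal(nrow(pool), 30)  # cap binds
  # kept features are exactly the top 30 by oriented AUC (ties by id)
  oa <- apply(X, 2, function(v) max(compute_auc(v, labels),
                                    1 - compute_auc(v, labels)))
  want <- names(sort(oa, decreasing = TRUE))
  ord <- order(-oa, names(oa))
  expect_setequal(pool$feature, names(oa)[ord][1:30])
  # all below threshold: that type contributes nothing -> empty pool errors
  Xn <- matrix(rep(c(1, 2), n / 2), n, 3,
               dimnames = list(NULL, c("c1", "c2", "c3")))
  expect_error(build_feature_pool(Xn, setNames(rep("snp", 3), colnames(Xn)),
                                  labels, auc_min = 0.99), "empty feature pool")
  # constant features never enter
  Xc <- cbind(X, const = 1)
  ftc <- setNames(rep("protein", k + 1), colnames(Xc))
  pool2 <- build_feature_pool(Xc, ftc, labels)
  expect_false("const" %in% pool2$feature)
})

test_that("model enumeration matches the binomial closed form", {
  expect_equal(length(enumerate_models(3)), 7)
  models10 <- enumerate_models(10)
  expect_equal(length(models10), 175)
  expect_equal(length(unique(lapply(models10, sort))), 175)
  for (k in c(5, 17, 40, 126, 200)) {
    want <- sum(choose(k, 1:3))
    if (k <= 40) expect_equal(length(enumerate_models(k)), want)
  }
  expect_equal(sum(choose(126, 1:3)), 333501)
  expect_error(enumerate_models(5, max_order = 0), "max_order")
})

test_that("the MCC obeys its extremes and zero-denominator convention", {
  expect_equal(matthews_cc(5, 5, 0, 0), 1)
  expect_equal(matthews_cc(0, 0, 5, 5), -1)
  expect_equal(matthews_cc(3, 0, 2, 0), 0)  # no observed negatives
  expect_error(matthews_cc(0, 0, 0, 0), "at least one")
  expect_error(matthews_cc(-1, 2, 0, 0), "non-negative")
  # spot-check the phi equivalence (full exhaustive sweep in the acceptance
  # suite)
  set.seed(3)
  for (i in 1:100) {
    cts <- as.vector(rmultinom(1, sample(4:20, 1), rep(0.25, 4)))
    phi <- phi_from_counts(cts[1], cts[2], cts[3], cts[4])
    if (!is.na(phi))
      expect_equal(matthews_cc(cts[1], cts[2], cts[3], cts[4]), phi)
  }
})

test_that("the compiled logistic fit agrees with glm at tiny penalty", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -0.5, 0.2)))
  beta <- cpp_fit_logistic(X, as.integer(y), 1e-10)
  ref <- unname(coef(glm(y ~ X, family = binomial())))
  expect_lt(max(abs(beta - ref)), 1e-4)
})

test_that("a perfectly separating variable scores a perfect model", {
  X <- matrix(c(rep(1, 30), rep(-1, 10)), ncol = 1,
              dimnames = list(NULL, "sep"))
  labels <- rep(c(1, 0), c(30, 10))
  res <- evaluate_model("sep", X, labels, n_subsamples = 50, seed = 3)
  expect_equal(res$mcc, 1)
  expect_equal(res$mmce, 0)
  expect_equal(res$ppv, 1)
  expect_equal(res$n_complete, 40)
})

test_that("label-independent variables score near zero on average", {
  set.seed(9)
  mccs <- vapply(1:200, function(i) {
    X <- matrix(rnorm(45), ncol = 1, dimnames = list(NULL, "noise"))
    labels <- rep(c(1, 0), c(35, 10))
    evaluate_model("noise", X, labels, n_subsamples = 20, seed = i)$mcc
  }, 0)
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("missing cells reduce a model to its complete cases", {
  set.seed(10)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  labels <- rep(c(1, 0), c(45, 15))
  X[1:5, 1] <- NA
  res <- evaluate_model(c("a", "b"), X, labels, n_subsamples = 20, seed = 1)
  expect_equal(res$n_complete, 55)
})

test_that("a small pool search returns every model and is reproducible", {
  set.seed(11)
  n <- 50
  labels <- rep(c(1, 0), c(38, 12))
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x", "y", "z")))
  X[labels == 1, 1] <- X[labels == 1, 1] + 1.5
  ft <- setNames(rep("protein", 3), colnames(X))
  res <- run_search(X, labels, colnames(X), n_subsamples = 50, seed = 5)
  expect_equal(nrow(res), 7)
  res2 <- run_search(X, labels, colnames(X), n_subsamples = 50, seed = 5)
  expect_identical(res, res2)
  # enumeration/evaluation order does not matter: reversed pool, same models
  res3 <- run_search(X, labels, rev(colnames(X)), n_subsamples = 50, seed = 5)
  key <- function(df) {
    sets <- lapply(strsplit(df$model, " + ", fixed = TRUE), sort)
    df$mcc[order(vapply(sets, paste, "", collapse = "|"))]
  }
  expect_equal(key(res), key(res3))
})

test_that("an independent naive implementation finds the same best model", {
  # separate code path: plain R loop over glm fits with its own RNG,
  # re-implementing the same scheme (stratified 2/3 split, training
  # standardisation, threshold tuned on training MCC); with a clear planted
  # signal both engines must agree on the winning variable set
  set.seed(13)
  n <- 60
  labels <- rep(c(1, 0), c(42, 18))
  k <- 6
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, sprintf("v%d", 1:k)))
  for (j in c(2, 4, 6)) X[labels == 1, j] <- X[labels == 1, j] + 1.6
  res <- run_search(X, labels, colnames(X), n_subsamples = 100, seed = 21)

  tune_thr <- function(pr, lab) {
    cand <- c(sort(unique(pr)), max(pr) + 1)
    mccs <- vapply(cand, function(t) {
      pred <- as.integer(pr >= t)
      matthews_cc(sum(pred & lab), sum(!pred & !lab),
                  sum(pred & !lab), sum(!pred & lab))
    }, 0)
    cand[which.max(mccs)]
  }
  naive_score <- function(vars) {
    set.seed(99)
    mean(replicate(100, {
      pos <- sample(which(labels == 1)); neg <- sample(which(labels == 0))
      tr <- c(pos[1:28], neg[1:12]); te <- setdiff(seq_len(n), tr)
      mu <- colMeans(X[tr, vars, drop = FALSE])
      sd_ <- apply(X[tr, vars, drop = FALSE], 2, sd)
      Z <- scale(X[, vars, drop = FALSE], mu, sd_)
      d <- data.frame(y = labels, Z)
      fit <- suppressWarnings(glm(y ~ ., data = d[tr, ], family = binomial()))
      thr <- tune_thr(suppressWarnings(
        predict(fit, d[tr, ], type = "response")), labels[tr])
      pr <- suppressWarnings(predict(fit, d[te, ], type = "response"))
      pred <- as.integer(pr >= thr)
      matthews_cc(sum(pred & labels[te]), sum(!pred & !labels[te]),
                  sum(pred & !labels[te]), sum(!pred & labels[te]))
    }))
  }
  models <- enumerate_models(k)
  naive <- vapply(models, function(m) naive_score(colnames(X)[m]), 0)
  best_naive <- sort(colnames(X)[models[[which.max(naive)]]])
  best_engine <- sort(strsplit(res$model[1], " + ", fixed = TRUE)[[1]])
  expect_equal(best_engine, best_naive)
})

test_that("pure-noise additions cannot buy more than sampling error", {
  set.seed(17)
  n <- 60
  labels <- rep(c(1, 0), c(45, 15))
  X <- cbind(sig = rnorm(n) + 1.4 * labels, noise = rnorm(n))
  base <- evaluate_model("sig", X, labels, n_subsamples = 200, seed = 4)
  plus <- evaluate_model(c("sig", "noise"), X, labels, n_subsamples = 200,
                         seed = 4)
  expect_lt(plus$mcc - base$mcc, 0.05)
})

test_that("permutation p-values hit the boundary cases", {
  set.seed(23)
  n <- 60
  labels <- rep(c(1, 0), c(45, 15))
  k <- 10
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, sprintf("w%d", 1:k)))
  X[labels == 1, 1:3] <- X[labels == 1, 1:3] + 2.5  # overwhelming signal
  ft <- setNames(rep("protein", k), colnames(X))
  pool <- build_feature_pool(X, ft, labels, 0.6, 10)
  res <- run_search(X, labels, pool, n_subsamples = 30, seed = 2)
  pt <- permutation_test(X, ft, labels, res, n_perm = 4, perm_subsamples = 20,
                         per_type_cap = 10, seed = 31)
  # a model above every pooled null value gets p = 0
  expect_equal(pt$p_value[1], 0)
  expect_gt(attr(pt, "n_null"), 0)
  expect_true(is.numeric(attr(pt, "mcc_threshold")))
  # familywise variant pools one maximum per permutation
  ptm <- permutation_test(X, ft, labels, res, n_perm = 4,
                          perm_subsamples = 20, per_type_cap = 10, seed = 31,
                          null_stat = "max")
  expect_equal(length(attr(ptm, "null_mcc")), 4)
  expect_error(permutation_test(X, ft, labels, res, n_perm = 1, seed = 1),
               "at least 2")
})
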