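test_that("the missingness filter applies type-specific thresholds exactly", {
  n <- 100
  mk <- function(frac_seen, type) {
    v <- matrix(1, 1, n, dimnames = list("a", sprintf("s%03d", 1:n)))
    v[1, seq_len(round((1 - frac_seen) * n))] <- NA
    analyte_matrix(v, type, if (type == "snp") "categorical" else "log2")
  }
  expect_equal(nrow(filter_missingness(mk(0.69, "protein"))), 0)
  expect_equal(nrow(filter_missingness(mk(0.70, "protein"))), 1)
  expect_equal(nrow(filter_missingness(mk(0.49, "rna"))), 0)
  expect_equal(nrow(filter_missingness(mk(0.50, "metabolite"))), 1)
  # zeros count as unseen even when unmasked
  v <- matrix(c(rep(0, 60), rep(2, 40)), 1, n,
              dimnames = list("a", sprintf("s%03d", 1:n)))
  expect_equal(nrow(filter_missingness(analyte_matrix(v, "rna", "linear"))), 0)
  # fully observed matrix unchanged
  set.seed(2)
  v <- matrix(rnorm(300) + 10, 3, 100,
              dimnames = list(c("a", "b", "c"), sprintf("s%03d", 1:100)))
  m <- analyte_matrix(v, "protein", "log2")
  out <- filter_missingness(m)
  expect_equal(out[, ], v)
})

test_that("random masks match brute-force retention fractions", {
  set.seed(9)
  n <- 60
  v <- matrix(rnorm(100 * n) + 5, 100, n,
              dimnames = list(sprintf("a%03d", 1:100), sprintf("s%03d", 1:n)))
  v[runif(length(v)) < 0.4] <- NA
  m <- analyte_matrix(v, "metabolite", "log2")
  kept <- rownames(filter_missingness(m))
  brute <- rownames(v)[rowMeans(!is.na(v) & v != 0) >= 0.5]
  expect_setequal(kept, brute)
})

test_that("the assumption gate picks the right two-group branch", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  res <- two_group_test(x, y)
  expect_equal(res$test, "t")
  # closed-form pooled-variance t as independent oracle
  sp <- sqrt(((29) * var(x) + (29) * var(y)) / 58)
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(1 / 30 + 1 / 30))
  p_ref <- 2 * pt(-abs(tstat), df = 58)
  expect_lt(abs(res$p - p_ref), 1e-10)

  skewed <- exp(rnorm(30, 0, 1.5))
  expect_equal(two_group_test(skewed, y)$test, "wilcoxon")

  same <- rep(c(1, 2, 3), 4)
  res <- two_group_test(same, same)
  expect_gt(res$p, 0.9)
  expect_equal(median_fold_change(same, same, "log2")$fold, 1)
})

test_that("two-group p-values are uniform under the null in both branches", {
  set.seed(77)
  sims <- replicate(2000, {
    x <- rnorm(25); y <- rnorm(25)
    r <- two_group_test(x, y)
    c(p = r$p, t = r$test == "t")
  })
  p_t <- sims[1, sims[2, ] == 1]
  p_w <- sims[1, sims[2, ] == 0]
  expect_gt(stats::ks.test(p_t, "punif")$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(p_w, "punif")$p.value), 0.01)
})

test_that("three-group testing flags planted gradients and only those", {
  # symmetric identical groups: statistic 0, p = 1
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- three_group_test(g)
  expect_equal(res$kw_p, 1)
  # planted control < TSC-no-epi < TSC-epi gradient: omnibus significant and
  # the epilepsy-vs-control contrast flagged
  set.seed(12)
  g <- list(rnorm(34, 10, 0.3), rnorm(9, 10.6, 0.3), rnorm(31, 11.2, 0.3))
  res <- three_group_test(g, scale = "log2")
  expect_lt(res$kw_p, 1e-6)
  expect_false(is.null(res$pairs))
  flag13 <- res$pairs$significant[res$pairs$g1 == 1 & res$pairs$g2 == 3]
  expect_true(flag13)
  # constant data: p 1, no post-hoc
  res <- three_group_test(list(rep(1, 5), rep(1, 5), rep(1, 5)))
  expect_equal(res$kw_p, 1)
  expect_null(res$pairs)
})

test_that("BH adjustment matches hand and brute-force computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # permutation invariance
  p <- runif(15)
  o <- sample(15)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("median fold changes follow scale and antisymmetry rules", {
  expect_equal(median_fold_change(c(3, 3, 3), c(2, 2, 2), "log2")$fold, 2)
  expect_equal(median_fold_change(c(3, 3), c(2, 2), "log2")$direction, "up")
  expect_equal(median_fold_change(c(4, 4), c(2, 2), "linear")$fold, 2)
  expect_true(is.na(median_fold_change(c(4, 4), c(0, 0), "linear")$fold))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(7)
    f1 <- median_fold_change(x, y, "log2")$fold
    f2 <- median_fold_change(y, x, "log2")$fold
    expect_equal(f1, 1 / f2)
  }
})

test_that("a planted 52-fold drug effect is recovered at realistic noise", {
  folds <- vapply(1:20, function(s) {
    set.seed(600 + s)
    x <- 12 + log2(52) + rnorm(72, 0, 0.3)
    y <- 12 + rnorm(28, 0, 0.3)
    median_fold_change(x, y, "log2")$fold
  }, 0)
  expect_true(median(folds) > 45 && median(folds) < 60)
  expect_gte(sum(folds > 45 & folds < 60), 18)
})

test_that("the dual-route rule keeps only jointly significant analytes", {
  r1 <- data.frame(analyte_id = c("a", "b", "c", "d"),
                   p_adj = c(0.01, 0.01, 0.2, 0.01),
                   fold = c(2, 2, 2, 1.2))
  r2 <- data.frame(analyte_id = c("a", "b", "c", "d"),
                   p_adj = c(0.01, 0.3, 0.01, 0.01),
                   fold = c(0.4, 2, 2, 2))
  out <- dual_method_intersect(r1, r2)
  # a: significant both routes (fold 0.4 = 2.5-fold down still passes);
  # b: tertile route not significant; c: mixed-model route not; d: fold gate
  expect_equal(out$analyte_id, "a")
  expect_error(dual_method_intersect(r1, r2[1:3, ]), "different analytes")
  empty <- r1[0, ]
  expect_equal(nrow(dual_method_intersect(empty, empty)), 0)
  # random flags equal independent set algebra
  set.seed(10)
  for (i in 1:10) {
    n <- 50
    ra <- data.frame(analyte_id = sprintf("x%02d", 1:n),
                     p_adj = runif(n), fold = exp(rnorm(n)))
    rb <- data.frame(analyte_id = sprintf("x%02d", 1:n),
                     p_adj = runif(n), fold = exp(rnorm(n)))
    sig <- function(df) df$analyte_id[df$p_adj < 0.05 &
                                        pmax(df$fold, 1 / df$fold) > 1.5]
    expect_setequal(dual_method_intersect(ra, rb)$analyte_id,
                    intersect(sig(ra), sig(rb)))
  }
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- sprintf("u%02d", 1:20)
  pw <- list(hit_pathway = universe[1:5], other = universe[6:9])
  res <- hypergeom_enrich(universe[1:5], pw, universe)
  # drawing all 5 pathway members in 5 draws: p = 1 / C(20,5)
  expect_equal(res$p[res$pathway == "hit_pathway"], 1 / choose(20, 5))
  expect_gt(res$p[res$pathway == "other"], 0.999)
  expect_error(hypergeom_enrich("zz", pw, universe), "within the universe")
  expect_error(hypergeom_enrich(character(), pw, character()), "empty")
  # simulation agrees with the hypergeometric tail
  set.seed(14)
  draws <- replicate(4000, length(intersect(sample(universe, 5),
                                            universe[1:5])))
  expect_lt(abs(mean(draws >= 2) -
                phyper(1, 5, 15, 5, lower.tail = FALSE)), 0.02)
})

test_that("comparison group assembly matches a brute-force re-derivation", {
  co <- generate_cohort(null_config(), seed = 19)
  meta <- co$meta
  for (str in c("strict", "relaxed")) {
    g <- comparison_groups(meta, "Vb", str)
    ctl <- meta$group == "control" & meta$age_weeks <= 17
    enr <- meta$group == "tsc" & meta$timepoint_label == "enrollment"
    g2 <- enr & !meta$seizure_history
    g3 <- enr & meta$seizure_history & !meta$seizure_at_draw
    if (str == "strict") {
      g2 <- g2 & !meta$presymptomatic_vgb & !meta$abnormal_eeg_at_draw
      g3 <- g3 & !(meta$abnormal_eeg_at_draw & !meta$seizure_at_draw)
    }
    expect_setequal(g$control, meta$sample_id[ctl])
    expect_setequal(g$tsc_no_epilepsy, meta$sample_id[g2])
    expect_setequal(g$tsc_epilepsy, meta$sample_id[g3])
    # relaxed groups 2 and 3 are supersets of the strict ones
  }
  gs <- comparison_groups(meta, "Vb", "strict")
  gr <- comparison_groups(meta, "Vb", "relaxed")
  expect_true(all(gs$tsc_no_epilepsy %in% gr$tsc_no_epilepsy))
  expect_true(all(gs$tsc_epilepsy %in% gr$tsc_epilepsy))
  # 24-month three-group split covers presymptomatic treatment correctly
  va <- comparison_groups(meta, "Va")
  m24 <- meta[meta$timepoint_label == "24m", ]
  expect_equal(length(va$seizure_free_presym),
               sum(!m24$seizure_history & m24$presymptomatic_vgb))
})

test_that("a null cohort produces no dual-route significant analytes", {
  hit_counts <- vapply(1:3, function(s) {
    cfg <- null_config(n_analytes = c(protein = 120, metabolite = 0,
                                      rna = 0, mirna = 0, snp = 0),
                       missingness_quantile = c(protein = 0, metabolite = 0,
                                                rna = 0, mirna = 0))
    co <- generate_cohort(cfg, seed = 700 + s)
    m <- co$matrices$protein
    fit <- fit_lmm_age_model(m, co$meta)
    lmm <- list(protein = apply_lmm_correction(m, co$meta, fit))
    zt <- list(protein = age_tertile_correct(m, co$meta))
    res <- run_comparison("Vb", lmm, zt, co$meta, stringency = "relaxed")
    nrow(res)
  }, 0)
  expect_lte(sum(hit_counts), 1)
})

test_that("a planted three-group gradient is reported by the full comparison", {
  cfg <- null_config(n_analytes = c(protein = 60, metabolite = 0, rna = 0,
                                    mirna = 0, snp = 0),
                     missingness_quantile = c(protein = 0, metabolite = 0,
                                              rna = 0, mirna = 0))
  cfg$group_effect_spec <- data.frame(analyte = sprintf("prot_%04d", 1:5),
                                      log2_step = 1.2)
  co <- generate_cohort(cfg, seed = 23)
  m <- co$matrices$protein
  fit <- fit_lmm_age_model(m, co$meta)
  lmm <- list(protein = apply_lmm_correction(m, co$meta, fit))
  zt <- list(protein = age_tertile_correct(m, co$meta))
  res <- run_comparison("Vb", lmm, zt, co$meta, stringency = "relaxed")
  expect_gte(sum(sprintf("prot_%04d", 1:5) %in% res$analyte_id), 4)
  # gradient direction: epilepsy group above control, as planted
  expect_true(all(res$fold[res$analyte_id %in% sprintf("prot_%04d", 1:5)] > 1))
})
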