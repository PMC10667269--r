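#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a prospective TSC infant cohort: 93 TSC
#' subjects sampled serially from enrollment (median age ~4.7 weeks) to 104
#' weeks plus 58 single-sample controls; per-analyte developmental
#' trajectories in four archetypes covering a type-specific fraction of
#' analytes (0.84 protein, 0.69 metabolite, 0.51 RNA); metabolite batch
#' offsets; multiplicative vigabatrin effects up to 52-fold; a three-level
#' group gradient (control < TSC-no-epilepsy < TSC-epilepsy) on selected
#' analytes; planted seizure-predictive analytes at a stated univariate AUC;
#' below-detection-limit missingness; and the 54/11 outcome imbalance among
#' the 65 classifier-eligible subjects (93 minus 7 entry-seizure, 14
#' presymptomatic-vigabatrin seizure-free, and 7 without a comparable
#' enrollment sample).
#'
#' @param n_tsc,n_control cohort sizes.
#' @param n_analytes named integer vector of analytes per data type
#'   (`protein`, `metabolite`, `rna`, `mirna`, `snp`); zero drops a type.
#' @param age_effect_fraction named fractions of age-affected analytes.
#' @param batch_count,batch_sd metabolite batch structure (log2 offset SD).
#' @param vgb_effect_spec data.frame `analyte`, `fold`: multiplicative
#'   vigabatrin effects planted on metabolites.
#' @param group_effect_spec data.frame `analyte`, `log2_step`: additive log2
#'   step per group level (control = 0, TSC no epilepsy = 1, TSC epilepsy =
#'   2), applied to enrollment-stage samples (age <= 17 weeks).
#' @param planted_predictors data.frame `analyte`, `auc`: seizure-predictive
#'   analytes; enrollment samples of subjects who develop seizures are
#'   shifted by `sqrt(2) * qnorm(auc)` total SDs (normal-theory AUC mapping).
#' @param missingness_quantile named per-type detection-limit quantiles;
#'   values below the type's quantile are masked (missing-not-at-random).
#' @param class_balance `c(seizure, seizure_free)` among eligible subjects.
#' @param exclusions `c(entry_seizure, presym_vgb_seizure_free,
#'   no_enrollment)` subject counts; with `class_balance` they must add up to
#'   `n_tsc`.
#' @param intercept_sd,resid_sd subject random-intercept and residual SD
#'   (log2 units).
#' @param amplitude_mean,amplitude_sd trajectory amplitude |N(mean, sd)|
#'   (log2 units) for age-affected analytes.
#' @param rna_dispersion negative-binomial size for RNA counts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tsc = 93, n_control = 58,
                          n_analytes = c(protein = 340, metabolite = 249,
                                         rna = 1000, mirna = 45, snp = 86),
                          age_effect_fraction = c(protein = 0.84,
                                                  metabolite = 0.69,
                                                  rna = 0.51, mirna = 0.50),
                          batch_count = 4, batch_sd = 0.6,
                          vgb_effect_spec = NULL,
                          group_effect_spec = NULL,
                          planted_predictors = NULL,
                          missingness_quantile = c(protein = 0.05,
                                                   metabolite = 0.03,
                                                   rna = 0, mirna = 0.02),
                          class_balance = c(seizure = 54, seizure_free = 11),
                          exclusions = c(entry_seizure = 7,
                                         presym_vgb_seizure_free = 14,
                                         no_enrollment = 7),
                          intercept_sd = 0.5, resid_sd = 0.2,
                          amplitude_mean = 1.5, amplitude_sd = 0.5,
                          rna_dispersion = 8) {
  if (is.null(vgb_effect_spec) && n_analytes[["metabolite"]] >= 30)
    vgb_effect_spec <- data.frame(
      analyte = sprintf("met_%04d", 3:30),
      fold = c(52, exp(seq(log(1.5), log(4.5), length.out = 27))))
  if (is.null(vgb_effect_spec))
    vgb_effect_spec <- data.frame(analyte = character(), fold = numeric())
  if (is.null(planted_predictors) &&
      n_analytes[["mirna"]] >= 2 && n_analytes[["protein"]] >= 1)
    planted_predictors <- data.frame(
      analyte = c("mir_01", "mir_02", "prot_0001"), auc = 0.85)
  if (is.null(planted_predictors))
    planted_predictors <- data.frame(analyte = character(), auc = numeric())
  if (is.null(group_effect_spec) &&
      n_analytes[["protein"]] >= 2 && n_analytes[["metabolite"]] >= 2 &&
      n_analytes[["rna"]] >= 4)
    group_effect_spec <- data.frame(
      analyte = c("prot_0002", "met_0002",
                  sprintf("rna_%05d", 1:4)),
      log2_step = 0.45)
  if (is.null(group_effect_spec))
    group_effect_spec <- data.frame(analyte = character(), log2_step = numeric())

  stopifnot(all(age_effect_fraction >= 0 & age_effect_fraction <= 1),
            all(vgb_effect_spec$fold > 0),
            all(planted_predictors$auc > 0.5 & planted_predictors$auc <= 1))
  if (sum(class_balance) + sum(exclusions) != n_tsc)
    stop("class_balance + exclusions must account for every TSC subject ",
         "(got ", sum(class_balance) + sum(exclusions), " vs n_tsc = ", n_tsc, ")")
  structure(list(n_tsc = n_tsc, n_control = n_control,
                 n_analytes = n_analytes,
                 age_effect_fraction = age_effect_fraction,
                 batch_count = batch_count, batch_sd = batch_sd,
                 vgb_effect_spec = vgb_effect_spec,
                 group_effect_spec = group_effect_spec,
                 planted_predictors = planted_predictors,
                 missingness_quantile = missingness_quantile,
                 class_balance = class_balance, exclusions = exclusions,
                 intercept_sd = intercept_sd, resid_sd = resid_sd,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 rna_dispersion = rna_dispersion),
            class = "cohort_config")
}

# trajectory archetypes, each scaled to [0, 1] over ages 0..104 weeks.
# All shapes saturate past ~40 weeks: developmental change concentrates in
# the first year, so the >40-week stratum carries minimal age effect (the
# property the drug-effect comparison relies on).
trajectory_shape <- function(archetype, age_weeks) {
  switch(archetype,
         none = rep(0, length(age_weeks)),
         monotone_up = 1 - exp(-age_weeks / 14),
         monotone_down = exp(-age_weeks / 40),
         # steep neonatal peak collapsing past ~10 weeks (alpha-fetoprotein
         # style decline)
         early_peak = exp(-0.5 * ((age_weeks - 5) / 8)^2),
         late_plateau = stats::plogis((age_weeks - 30) / 8),
         stop("unknown archetype: ", archetype))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# subject roster + longitudinal sampling schedule
build_metadata <- function(config) {
  cb <- config$class_balance; ex <- config$exclusions
  roles <- c(rep("eligible_seizure", cb[["seizure"]]),
             rep("eligible_seizure_free", cb[["seizure_free"]]),
             rep("entry_seizure", ex[["entry_seizure"]]),
             rep("presym_vgb_seizure_free", ex[["presym_vgb_seizure_free"]]),
             rep("no_enrollment", ex[["no_enrollment"]]))
  n_tsc <- config$n_tsc
  subj <- sprintf("tsc_%03d", seq_len(n_tsc))
  roles <- sample(roles)  # shuffle roles over subject ids

  acc <- new.env(parent = emptyenv())
  acc$subject_id <- acc$timepoint_label <- acc$group <- character()
  acc$age_weeks <- numeric()
  acc$vgb <- acc$seizure_history <- acc$seizure_before_draw <-
    acc$abnormal_eeg_at_draw <- acc$seizure_at_draw <-
    acc$drug_resistant_24m <- acc$presymptomatic_vgb <- logical()
  add <- function(subject, age, label, vgb, sz_hist, sz_before, eeg, sz_now,
                  dre, presym, group = "tsc") {
    acc$subject_id <- c(acc$subject_id, subject)
    acc$age_weeks <- c(acc$age_weeks, age)
    acc$timepoint_label <- c(acc$timepoint_label, label)
    acc$vgb <- c(acc$vgb, vgb)
    acc$group <- c(acc$group, group)
    acc$seizure_history <- c(acc$seizure_history, sz_hist)
    acc$seizure_before_draw <- c(acc$seizure_before_draw, sz_before)
    acc$abnormal_eeg_at_draw <- c(acc$abnormal_eeg_at_draw, eeg)
    acc$seizure_at_draw <- c(acc$seizure_at_draw, sz_now)
    acc$drug_resistant_24m <- c(acc$drug_resistant_24m, dre)
    acc$presymptomatic_vgb <- c(acc$presymptomatic_vgb, presym)
  }

  for (i in seq_len(n_tsc)) {
    role <- roles[i]; id <- subj[i]
    enroll_age <- min(17, max(0.3, stats::rlnorm(1, log(4.7), 0.79)))
    seizes <- role %in% c("eligible_seizure", "entry_seizure", "no_enrollment")
    presym <- role %in% c("presym_vgb_seizure_free", "no_enrollment")
    sz_age <- if (seizes) {
      if (role == "entry_seizure") enroll_age
      else min(100, max(enroll_age + 1, stats::rlnorm(1, log(20), 0.6)))
    } else Inf
    eeg_age <- if (seizes && role != "entry_seizure")
      max(enroll_age + 0.5, sz_age - stats::runif(1, 2, 10))
    else if (presym) stats::runif(1, 4, 20) else Inf
    vgb_start <- if (presym) eeg_age else if (seizes) sz_age else Inf
    eeg_at_enroll <- (seizes || presym) && stats::runif(1) < 0.25
    dre <- seizes && stats::runif(1) < 0.5

    at <- function(a) list(vgb = a >= vgb_start, sb = a >= sz_age)
    if (role != "no_enrollment") {
      s <- at(enroll_age)
      add(id, enroll_age, "enrollment", s$vgb, seizes, s$sb,
          eeg_at_enroll || role == "entry_seizure",
          role == "entry_seizure", dre, presym)
    }
    if (is.finite(eeg_age) && eeg_age < 100) {
      s <- at(eeg_age)
      add(id, eeg_age, "eeg", s$vgb, seizes, s$sb, TRUE, FALSE, dre, presym)
    }
    if (seizes && role != "entry_seizure" && sz_age < 100) {
      s <- at(sz_age)
      add(id, sz_age, "seizure", s$vgb, seizes, TRUE, TRUE, TRUE, dre, presym)
    }
    if (role == "no_enrollment") {
      s <- at(26)
      add(id, 26, "routine", s$vgb, seizes, s$sb, FALSE, FALSE, dre, presym)
    }
    if (!seizes && !presym) {
      a <- sample(c(26, 52), 1)
      add(id, a, "routine", FALSE, FALSE, FALSE, FALSE, FALSE, dre, presym)
    }
    s <- at(104)
    add(id, 104, "24m", s$vgb, seizes, s$sb, FALSE, FALSE, dre, presym)
  }
  for (i in seq_len(config$n_control)) {
    young <- stats::runif(1) < 0.6
    a <- if (young) stats::runif(1, 0.5, 17) else stats::runif(1, 17, 104)
    add(sprintf("ctl_%03d", i), a, "control", FALSE, FALSE, FALSE, FALSE,
        FALSE, NA, FALSE, group = "control")
  }
  meta <- data.frame(subject_id = acc$subject_id, age_weeks = acc$age_weeks,
                     timepoint_label = acc$timepoint_label, vgb = acc$vgb,
                     group = acc$group, seizure_history = acc$seizure_history,
                     seizure_before_draw = acc$seizure_before_draw,
                     abnormal_eeg_at_draw = acc$abnormal_eeg_at_draw,
                     seizure_at_draw = acc$seizure_at_draw,
                     drug_resistant_24m = acc$drug_resistant_24m,
                     presymptomatic_vgb = acc$presymptomatic_vgb,
                     stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s_%04d", seq_len(nrow(meta)))
  meta$batch <- rep_len(seq_len(max(1, config$batch_count)),
                        nrow(meta))[sample.int(nrow(meta))]
  sample_metadata(meta[, c("sample_id", "subject_id", "age_weeks", "batch",
                           "vgb", "group", "seizure_history",
                           "seizure_before_draw", "abnormal_eeg_at_draw",
                           "seizure_at_draw", "drug_resistant_24m",
                           "presymptomatic_vgb", "timepoint_label")])
}

#' Generate a fully labelled synthetic cohort
#'
#' Produces per-type analyte matrices, a sample metadata table, and a ground
#' truth ledger of every planted effect, deterministically for a given
#' `(config, seed)`. Values are built as baseline + age trajectory + subject
#' random intercept + batch offset (metabolites) + vigabatrin log2 effect +
#' group effect + planted predictive shift + Gaussian noise on the log2
#' scale; RNA is drawn as negative-binomial counts around the latent log2
#' mean. Values below the per-type detection-limit quantile are masked.
#' Planted predictor analytes carry no age trajectory and are never masked,
#' so their univariate AUC follows the normal-theory mapping exactly.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; identical `(config, seed)` give bit-identical
#'   cohorts.
#' @return A list with `matrices` (named list of [analyte_matrix()]), `meta`
#'   (sample metadata), `truth` (per-analyte ground-truth data.frame), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    meta <- build_metadata(config)
    n_s <- nrow(meta)
    group_level <-ifelse(meta$group == "control", 0,
                          ifelse(meta$seizure_history, 2, 1))
    total_sd <- sqrt(config$intercept_sd^2 + config$resid_sd^2)

    archetypes <- c("monotone_up", "monotone_down", "early_peak",
                    "late_plateau")
    base_mu <- c(protein = 20, metabolite = 16, rna = 5, mirna = 12)
    subjects <- unique(meta$subject_id)

    truth <- list()
    matrices <- list()
    planted <- config$planted_predictors
    genr <- config$group_effect_spec

    for (type in c("protein", "metabolite", "rna", "mirna")) {
      k <- config$n_analytes[[type]]
      if (is.na(k) || k < 1) next
      ids <- switch(type,
                    protein = sprintf("prot_%04d", seq_len(k)),
                    metabolite = sprintf("met_%04d", seq_len(k)),
                    rna = sprintf("rna_%05d", seq_len(k)),
                    mirna = sprintf("mir_%02d", seq_len(k)))
      frac <- config$age_effect_fraction[[type]]
      if (is.null(frac) || is.na(frac)) frac <- 0
      is_planted <- ids %in% planted$analyte
      age_affected <- stats::runif(k) < frac & !is_planted
      arch <- ifelse(age_affected, sample(archetypes, k, replace = TRUE),
                     "none")
      amp <- ifelse(age_affected,
                    abs(stats::rnorm(k, config$amplitude_mean,
                                     config$amplitude_sd)), 0)
      baseline <- stats::rnorm(k, base_mu[[type]], 1.5)
      u <- matrix(stats::rnorm(k * length(subjects), 0, config$intercept_sd),
                  nrow = k, dimnames = list(ids, subjects))
      vals <- matrix(0, nrow = k, ncol = n_s,
                     dimnames = list(ids, meta$sample_id))
      for (a in seq_len(k)) {
        vals[a, ] <- baseline[a] +
          amp[a] * trajectory_shape(arch[a], meta$age_weeks) +
          u[a, meta$subject_id] +
          stats::rnorm(n_s, 0, config$resid_sd)
      }
      # batch offsets: metabolites only
      batch_off <- rep(0, max(meta$batch))
      if (type == "metabolite" && config$batch_count > 1) {
        batch_off <- stats::rnorm(config$batch_count, 0, config$batch_sd)
        vals <- vals + matrix(batch_off[meta$batch], nrow = k, ncol = n_s,
                              byrow = TRUE)
      }
      # group gradient, planted on the enrollment-stage window (age <= 17
      # weeks): a lifelong subject-constant shift would be absorbed into the
      # subject random intercept of the mixed-model age correction and
      # subtracted away, so the gradient is modelled as early-life biology
      g_step <- stats::setNames(rep(0, k), ids)
      hit <- intersect(ids, genr$analyte)
      if (length(hit)) {
        g_step[hit] <- genr$log2_step[match(hit, genr$analyte)]
        early <- as.numeric(meta$age_weeks <= 17)
        vals[hit, ] <- vals[hit, , drop = FALSE] +
          outer(g_step[hit], group_level * early)
      }
      # planted predictive shift on enrollment samples of seizure subjects
      delta <- stats::setNames(rep(0, k), ids)
      hit <- intersect(ids, planted$analyte)
      if (length(hit)) {
        delta[hit] <- sqrt(2) *
          stats::qnorm(planted$auc[match(hit, planted$analyte)]) * total_sd
        target <- meta$timepoint_label == "enrollment" & meta$seizure_history
        vals[hit, target] <- vals[hit, target, drop = FALSE] + delta[hit]
      }
      vfold <- stats::setNames(rep(1, k), ids)
      scale <- "log2"
      if (type == "rna") {
        mu <- 2^vals * exp(stats::rnorm(n_s, 0, 0.2))[col(vals)]
        vals <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = config$rna_dispersion),
                       nrow = k, dimnames = dimnames(vals))
        scale <- "linear"
      }
      m <- analyte_matrix(vals, data_type = type, scale = scale)
      # vigabatrin effects: metabolites only, via the same operation the
      # tests exercise directly
      if (type == "metabolite" && nrow(config$vgb_effect_spec)) {
        spec <- config$vgb_effect_spec[
          config$vgb_effect_spec$analyte %in% ids, , drop = FALSE]
        if (nrow(spec)) {
          m <- plant_vgb_effect(m, meta, spec)
          vfold[spec$analyte] <- spec$fold
        }
      }
      # detection-limit masking (never on planted predictors)
      q <- config$missingness_quantile[[type]]
      if (!is.null(q) && !is.na(q) && q > 0) {
        thr <- stats::quantile(as.numeric(unclass(m)), q, na.rm = TRUE)
        mask <- unclass(m) < thr
        mask[is_planted, ] <- FALSE
        v2 <- unclass(m); v2[mask] <- NA
        m <- amx_update(m, v2)
      }
      matrices[[type]] <- m
      truth[[type]] <- data.frame(
        analyte_id = ids, data_type = type, archetype = arch,
        amplitude = amp, baseline = baseline,
        vgb_log2fold = log2(vfold), group_log2_step = unname(g_step),
        planted_delta = unname(delta), stringsAsFactors = FALSE)
    }
    # SNPs: pre-encoded binary carrier matrix
    k <- config$n_analytes[["snp"]]
    if (!is.na(k) && k >= 1) {
      ids <- sprintf("snp_%02d", seq_len(k))
      maf <- stats::runif(k, 0.1, 0.5)
      carrier_p <- 1 - (1 - maf)^2
      subj_carrier <- matrix(stats::rbinom(k * length(subjects), 1,
                                           rep(carrier_p, length(subjects))),
                             nrow = k, dimnames = list(ids, subjects))
      vals <- subj_carrier[, meta$subject_id, drop = FALSE]
      colnames(vals) <- meta$sample_id
      matrices$snp <- analyte_matrix(vals, data_type = "snp",
                                     scale = "categorical")
      truth$snp <- data.frame(analyte_id = ids, data_type = "snp",
                              archetype = "none", amplitude = 0,
                              baseline = carrier_p, vgb_log2fold = 0,
                              group_log2_step = 0, planted_delta = 0,
                              stringsAsFactors = FALSE)
    }
    list(matrices = matrices, meta = meta,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         config = config)
  })
}

#' Plant a multiplicative vigabatrin effect
#'
#' Multiplies exposed samples (metadata `vgb` flag) of the named analytes by
#' a fold change; on log2-scale matrices the effect is applied additively as
#' `log2(fold)`.
#'
#' @param matrix an [analyte_matrix()] on log2 or linear scale.
#' @param meta sample metadata aligned with the matrix columns.
#' @param spec data.frame with columns `analyte` and `fold` (> 0).
#' @return The modified `analyte_matrix`.
#' @export
plant_vgb_effect <- function(matrix, meta, spec) {
  stopifnot(inherits(matrix, "analyte_matrix"), all(spec$fold > 0))
  missing_ids <- setdiff(spec$analyte, rownames(matrix))
  if (length(missing_ids))
    stop("analyte(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  exposed <- meta$vgb[match(colnames(matrix), meta$sample_id)]
  if (any(is.na(exposed))) stop("matrix columns missing from metadata")
  v <- unclass(matrix)
  for (i in seq_len(nrow(spec))) {
    a <- spec$analyte[i]; f <- spec$fold[i]
    if (amx_scale(matrix) == "log2")
      v[a, exposed] <- v[a, exposed] + log2(f)
    else
      v[a, exposed] <- v[a, exposed] * f
  }
  amx_update(matrix, v)
}
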