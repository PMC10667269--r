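#' Validate a sample-metadata table
#'
#' The per-sample covariate table shared by every stage. Required columns:
#' \describe{
#'   \item{sample_id, subject_id}{identifiers; `subject_id` is the grouping
#'     factor of the mixed-model age correction.}
#'   \item{age_weeks}{non-negative postnatal age at draw, in weeks.}
#'   \item{batch}{integer measurement batch (metabolites).}
#'   \item{vgb}{logical, on vigabatrin at the time of draw.}
#'   \item{group}{`"control"` or `"tsc"`.}
#'   \item{seizure_history}{logical, subject developed clinical or
#'     electrographic seizures at any point up to the 24-month endpoint.}
#'   \item{seizure_before_draw}{logical, seizures before/at this draw.}
#'   \item{abnormal_eeg_at_draw, seizure_at_draw}{logical event flags.}
#'   \item{drug_resistant_24m}{logical or `NA` (controls).}
#'   \item{presymptomatic_vgb}{logical, VGB started before any seizure.}
#'   \item{timepoint_label}{protocol label, e.g. `"enrollment"`, `"eeg"`,
#'     `"seizure"`, `"routine"`, `"24m"`.}
#' }
#'
#' @param meta a data.frame.
#' @return The validated data.frame (invisibly classed `sample_metadata`).
#' @export
sample_metadata <- function(meta) {
  req <- c("sample_id", "subject_id", "age_weeks", "batch", "vgb", "group",
           "seizure_history", "seizure_before_draw", "abnormal_eeg_at_draw",
           "seizure_at_draw", "drug_resistant_24m", "presymptomatic_vgb",
           "timepoint_label")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  if (any(!is.finite(meta$age_weeks)) || any(meta$age_weeks < 0))
    stop("age_weeks must be finite and non-negative")
  if (!all(meta$group %in% c("control", "tsc")))
    stop("group must be 'control' or 'tsc'")
  ctrl <- meta[meta$group == "control", ]
  if (nrow(ctrl) && anyDuplicated(ctrl$subject_id))
    stop("controls must have exactly one sample per subject")
  bad <- !meta$seizure_history & meta$seizure_at_draw
  if (any(bad))
    stop("contradictory flags (seizure_at_draw without seizure_history) for: ",
         paste(meta$sample_id[bad], collapse = ", "))
  class(meta) <- unique(c("sample_metadata", class(meta)))
  invisible(meta)
}

#' Read a sample-metadata TSV
#' @param path file path (tab-separated, header line).
#' @return A validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  for (col in c("vgb", "seizure_history", "seizure_before_draw",
                "abnormal_eeg_at_draw", "seizure_at_draw",
                "drug_resistant_24m", "presymptomatic_vgb"))
    meta[[col]] <- as.logical(meta[[col]])
  sample_metadata(meta)
}

#' Write a sample-metadata TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign postnatal ages to the three fixed age tertiles
#'
#' The strata are fixed constants of the analysis: T1 = \[0, 10\] weeks,
#' T2 = (10, 40\] weeks, T3 = (40, Inf) weeks. Integer-week ages 10 and 40
#' close the lower strata; every finite non-negative age maps to exactly one
#' tertile.
#'
#' @param age_weeks numeric vector of non-negative ages in weeks.
#' @return A factor with levels `T1`, `T2`, `T3`.
#' @export
age_tertile <- function(age_weeks) {
  if (any(!is.finite(age_weeks)) || any(age_weeks < 0))
    stop("ages must be finite and non-negative")
  cut(age_weeks, breaks = c(-Inf, 10, 40, Inf), labels = c("T1", "T2", "T3"),
      right = TRUE)
}

#' Select the classifier cohort and its outcome labels
#'
#' One enrollment sample per TSC subject (the minimum-age sample labelled
#' `"enrollment"`, ties broken by sample id), then removal of the union of
#' three exclusion sets: (a) subjects with subclinical seizures at study
#' entry, (b) subjects presymptomatically treated with vigabatrin who never
#' developed seizures, and (c) subjects with no comparable enrollment sample.
#' The outcome label is seizure vs seizure-free by 24 months.
#'
#' @param meta validated sample metadata.
#' @return A data.frame with one row per retained subject:
#'   `subject_id`, `sample_id` (the enrollment sample), `label`
#'   (1 = seizures by 24 months, 0 = seizure-free), and an `exclusions`
#'   attribute recording the three sets.
#' @export
select_classifier_cohort <- function(meta) {
  meta <- sample_metadata(as.data.frame(meta))
  tsc <- meta[meta$group == "tsc", , drop = FALSE]
  subjects <- unique(tsc$subject_id)
  enr <- tsc[tsc$timepoint_label == "enrollment", , drop = FALSE]
  enr <- enr[order(enr$subject_id, enr$age_weeks, enr$sample_id), ]
  enr <- enr[!duplicated(enr$subject_id), , drop = FALSE]

  subj_flag <- function(flag) unique(tsc$subject_id[flag])
  no_sample <- setdiff(subjects, enr$subject_id)
  entry_seizure <- enr$subject_id[enr$seizure_at_draw]
  presym_sf <- subj_flag(tsc$presymptomatic_vgb & !tsc$seizure_history)
  excluded <- union(union(no_sample, entry_seizure), presym_sf)

  keep <- enr[!(enr$subject_id %in% excluded), , drop = FALSE]
  out <- data.frame(subject_id = keep$subject_id,
                    sample_id = keep$sample_id,
                    label = as.integer(keep$seizure_history),
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- list(entry_seizure = entry_seizure,
                                  presymptomatic_vgb_seizure_free = presym_sf,
                                  no_enrollment_sample = no_sample)
  out
}
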