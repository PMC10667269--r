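#' Analyte-by-sample matrix container
#'
#' The basic container used throughout the pipeline: a numeric analyte x
#' sample matrix with an explicit missing-value mask (`NA`), a data-type
#' label, and a scale flag. Protein, metabolite and miRNA values live on the
#' log2 scale; RNA is carried either as raw counts (`scale = "linear"`) or as
#' log2(CPM+1); SNP and clinical indicators are 0/1 categorical.
#'
#' @param values numeric matrix, analytes in rows, samples in columns;
#'   `NA` marks a missing (e.g. below-detection-limit) measurement.
#' @param data_type one of `"protein"`, `"metabolite"`, `"rna"`, `"mirna"`,
#'   `"snp"`, `"clinical"`.
#' @param scale one of `"log2"`, `"linear"`, `"categorical"`.
#' @return An object of class `analyte_matrix` (a numeric matrix with
#'   `data_type` and `scale` attributes and unique dimnames).
#' @export
analyte_matrix <- function(values,
                           data_type = c("protein", "metabolite", "rna",
                                         "mirna", "snp", "clinical"),
                           scale = c("log2", "linear", "categorical")) {
  data_type <- match.arg(data_type)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have analyte rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate analyte ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (data_type %in% c("snp", "clinical")) {
    if (scale != "categorical")
      stop("snp/clinical matrices must have scale = 'categorical'")
    obs <- values[!is.na(values)]
    if (length(obs) && !all(obs %in% c(0, 1)))
      stop("categorical matrices must contain only 0/1 after encoding")
  }
  structure(values, data_type = data_type, scale = scale,
            class = c("analyte_matrix", "matrix", "array"))
}

#' @export
print.analyte_matrix <- function(x, ...) {
  cat(sprintf("<analyte_matrix> %d analytes x %d samples, type=%s, scale=%s, %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "data_type"), attr(x, "scale"),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @rdname analyte_matrix
#' @param x an `analyte_matrix`.
#' @export
amx_data_type <- function(x) attr(x, "data_type")

#' @rdname analyte_matrix
#' @export
amx_scale <- function(x) attr(x, "scale")

#' Replace the value matrix of an analyte matrix, keeping its labels
#'
#' @param x an `analyte_matrix` template.
#' @param values replacement numeric matrix with identical dimnames.
#' @param scale optional new scale flag.
#' @return An `analyte_matrix` with the same `data_type` as `x`.
#' @export
amx_update <- function(x, values, scale = amx_scale(x)) {
  analyte_matrix(values, data_type = amx_data_type(x), scale = scale)
}

#' Read an analyte table from TSV/CSV
#'
#' Expects analytes as rows, samples as columns, the first column holding the
#' analyte id. Blank cells and `NA` are treated as missing and masked, never
#' imputed.
#'
#' @param path file path; comma- or tab-separated, inferred from the
#'   extension (`.csv` vs anything else) unless `sep` is given.
#' @param data_type,scale forwarded to [analyte_matrix()].
#' @param sep field separator; default inferred from the file extension.
#' @return An `analyte_matrix`.
#' @export
read_analyte_matrix <- function(path, data_type, scale, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate analyte ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(suppress))
      if (length(bad))
        stop(sprintf("non-numeric cell in %s: row '%s', column '%s'",
                     path, ids[bad[1]], names(vals)[j]))
      col <- suppress
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  analyte_matrix(m, data_type = data_type, scale = scale)
}

#' Write an analyte matrix to TSV/CSV
#'
#' Missing values are written as blank cells; [read_analyte_matrix()] of the
#' written file reproduces values and mask bit-exactly (values are printed at
#' full double precision).
#'
#' @param x an `analyte_matrix`.
#' @param path output path.
#' @param sep field separator; default inferred from the extension.
#' @export
write_analyte_matrix <- function(x, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(analyte_id = rownames(x),
                   apply(unclass(x), 2, function(v)
                     ifelse(is.na(v), "", sprintf("%.17g", v))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("analyte_id", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Convert an RNA count matrix to log2 counts-per-million
#'
#' Library sizes are estimated by median-of-ratios size factors (computed on
#' genes observed in every sample) rather than raw column totals, so that a
#' few strongly regulated genes cannot drag the scaling of all others; when
#' no gene is observed everywhere, raw totals are used.
#'
#' @param counts an `analyte_matrix` of RNA counts (`scale = "linear"`).
#' @return An `analyte_matrix` of log2(CPM + 1) values (`scale = "log2"`).
#' @export
rna_log2cpm <- function(counts) {
  stopifnot(inherits(counts, "analyte_matrix"))
  v <- unclass(counts)
  lib <- colSums(v, na.rm = TRUE)
  if (any(lib <= 0)) stop("library size must be positive for every sample")
  allpos <- rowSums(is.na(v) | v == 0) == 0
  size <- lib
  if (sum(allpos) >= 10) {
    logref <- rowMeans(log(v[allpos, , drop = FALSE]))
    sf <- apply(v[allpos, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - logref)))
    size <- sf * exp(mean(log(lib / sf)))  # back on the library-size scale
  }
  cpm <- sweep(v, 2, size, "/") * 1e6
  amx_update(counts, log2(cpm + 1), scale = "log2")
}
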