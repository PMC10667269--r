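#' Encode diploid SNP genotypes as binary risk-allele carriage
#'
#' Each genotype call (e.g. `"T/C"`) is collapsed to two categories:
#' 0 = major-allele homozygote, 1 = heterozygote or minor-allele homozygote.
#' Missing calls (`NA` or `"./."`) are masked.
#'
#' @param genotypes a sample x SNP data.frame or character matrix of unphased
#'   calls `"A/B"`; rownames (or a `sample_id` first column) identify samples.
#' @param major_allele named character vector (or two-column data.frame
#'   `snp`, `major`) giving the major allele per SNP.
#' @return An `analyte_matrix` (SNP x sample, `data_type = "snp"`,
#'   `scale = "categorical"`).
#' @export
encode_snp_genotypes <- function(genotypes, major_allele) {
  if (is.data.frame(major_allele))
    major_allele <- stats::setNames(as.character(major_allele[[2]]),
                                    as.character(major_allele[[1]]))
  if (is.data.frame(genotypes)) {
    if (names(genotypes)[1] %in% c("sample_id", "sample")) {
      rn <- as.character(genotypes[[1]])
      genotypes <- as.matrix(genotypes[-1])
      rownames(genotypes) <- rn
    } else genotypes <- as.matrix(genotypes)
  }
  snps <- colnames(genotypes)
  miss <- setdiff(snps, names(major_allele))
  if (length(miss))
    stop("no major allele stated for: ", paste(miss, collapse = ", "))
  enc <- matrix(NA_real_, nrow = length(snps), ncol = nrow(genotypes),
                dimnames = list(snps, rownames(genotypes)))
  for (s in snps) {
    calls <- genotypes[, s]
    ok <- !is.na(calls) & calls != "./."
    if (!any(ok)) next
    alleles <- strsplit(calls[ok], "/", fixed = TRUE)
    if (any(lengths(alleles) != 2))
      stop("malformed genotype call for ", s)
    maj <- major_allele[[s]]
    a1 <- vapply(alleles, `[`, "", 1)
    a2 <- vapply(alleles, `[`, "", 2)
    if (any(!nzchar(c(a1, a2))))
      stop("empty allele in call for ", s)
    # biallelic contract: exactly one alternate allele besides the major
    alt <- setdiff(unique(c(a1, a2)), maj)
    if (length(alt) > 1)
      stop(sprintf("SNP %s: allele(s) %s not in {major '%s', one alternate}",
                   s, paste(alt[-1], collapse = ","), maj))
    enc[s, which(ok)] <- as.numeric(!(a1 == maj & a2 == maj))
  }
  analyte_matrix(enc, data_type = "snp", scale = "categorical")
}
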