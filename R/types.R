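#' Construct a genotype matrix
#'
#' Container for hard-call dosages with per-SNP metadata. Dosages count
#' copies of the alternate allele, so values live in \{0, 1, 2\} with `NA`
#' for missing calls.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param snps data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref_allele`, `alt_allele`, and optionally `maf` (minor
#'   allele frequency in `[0, 0.5]`) and `hwe_p` (exact-test p in `(0, 1]`).
#' @param sample_ids character vector of sample labels, one per dosage row.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `snps`, `sample_ids`.
#' @export
genotype_matrix <- function(dosage, snps, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(is.data.frame(snps), nrow(snps) == ncol(dosage),
            length(sample_ids) == nrow(dosage))
  required <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0)
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in genotype data: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (any(snps$pos < 1, na.rm = TRUE)) stop("SNP positions must be >= 1")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0 && !all(bad %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or NA")
  if (!("maf" %in% names(snps))) snps$maf <- NA_real_
  if (!("hwe_p" %in% names(snps))) snps$hwe_p <- NA_real_
  if (any(snps$maf > 0.5 + 1e-12 | snps$maf < 0, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  dimnames(dosage) <- list(sample_ids, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Construct an expression matrix
#'
#' Log2-scale expression values, features in rows and samples in columns;
#' `NA` marks a missing (uncalled) measurement.
#'
#' @param values numeric matrix, features x samples, with feature ids as row
#'   names and sample ids as column names.
#' @param kind `"miRNA"` or `"mRNA"`.
#'
#' @return An object of class `expression_matrix`: a list with `values`,
#'   `kind`, `feature_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0(tolower(kind), "_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in expression matrix")
  structure(list(values = values, kind = kind,
                 feature_ids = rownames(values),
                 sample_ids = colnames(values)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d features x %d samples (%.2f%% missing)\n",
              x$kind, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a covariate table
#'
#' Sample-level covariates (age, sex, genotype principal components, ...)
#' aligned to the sample order of companion matrices. No missing values are
#' allowed once constructed.
#'
#' @param sample_ids character vector of sample labels.
#' @param ... named numeric vectors, one per covariate, or a single data
#'   frame of covariate columns.
#'
#' @return An object of class `covariate_table`: a data frame with a
#'   `sample_id` column followed by numeric covariate columns.
#' @export
covariate_table <- function(sample_ids, ...) {
  cols <- list(...)
  if (length(cols) == 1 && is.data.frame(cols[[1]])) cols <- as.list(cols[[1]])
  if (length(cols) == 0) stop("covariate_table needs at least one covariate")
  lens <- vapply(cols, length, integer(1))
  if (any(lens != length(sample_ids)))
    stop("covariate length does not match number of samples")
  if (any(vapply(cols, anyNA, logical(1))))
    stop("covariates must not contain missing values")
  out <- data.frame(sample_id = as.character(sample_ids), cols,
                    stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Extract the numeric covariate matrix from a covariate table
#' @param ct a [covariate_table()].
#' @return numeric matrix, samples x covariates.
#' @export
covariate_values <- function(ct) {
  stopifnot(inherits(ct, "covariate_table"))
  as.matrix(ct[, setdiff(names(ct), "sample_id"), drop = FALSE])
}

# empty association-record table with the canonical column order
empty_association_table <- function() {
  data.frame(x_id = character(0), y_id = character(0), beta = numeric(0),
             se = numeric(0), t = numeric(0), p = numeric(0),
             n = integer(0), q = numeric(0), stringsAsFactors = FALSE)
}
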