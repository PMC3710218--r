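#' Read a genotype matrix from VCF or a dosage TSV
#'
#' VCF `GT` fields are mapped `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> NA` (phased separators accepted). When `use_ds = TRUE` and a `DS`
#' FORMAT field is present, fractional dosages are read instead and rounded
#' to the nearest hard call. Multi-allelic VCF records are skipped with a
#' warning; only biallelic SNPs are supported.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage_tsv"`. A
#'   dosage TSV has SNP ids in the first column, sample ids in the header,
#'   and cells in \{0, 1, 2, NA\}; SNP metadata columns `chrom`, `pos`,
#'   `ref_allele`, `alt_allele` may precede the sample columns.
#' @param use_ds prefer the VCF `DS` field over `GT` when present.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv"),
                           use_ds = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") .read_genotypes_vcf(path, use_ds) else
    .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path, use_ds) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id in VCF: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  if (use_ds && "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- round(ds)
    dos[dos < 0] <- 0; dos[dos > 2] <- 2
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("\\|", "/", gt)
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt %in% c("0/0")] <- 0
    dos[gt %in% c("0/1", "1/0")] <- 1
    dos[gt %in% c("1/1")] <- 2
  }
  snps <- data.frame(snp_id = snp_id, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(t(dos), snps, sample_ids = colnames(dos))
  compute_maf(g)
}

.read_genotypes_tsv <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, " (line ", which(nf != nf[1])[1], ")")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "ref_allele", "alt_allele"), names(tab))
  sample_cols <- setdiff(names(tab)[-1], meta_cols)
  if (length(sample_cols) == 0) stop("no sample columns in ", path)
  snp_id <- as.character(tab[[1]])
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id in ", path, ": ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  dos <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(dos)) {
    suppressWarnings(num <- matrix(as.numeric(dos), nrow(dos), ncol(dos)))
    bad <- which(is.na(num) & !(dos %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric dosage at row %d, column '%s'",
                   bad[1, 1], sample_cols[bad[1, 2]]))
    dos <- num
  }
  snps <- data.frame(snp_id = snp_id,
                     chrom = if ("chrom" %in% meta_cols) tab$chrom else ".",
                     pos = if ("pos" %in% meta_cols) as.integer(tab$pos) else seq_along(snp_id),
                     ref_allele = if ("ref_allele" %in% meta_cols) tab$ref_allele else "A",
                     alt_allele = if ("alt_allele" %in% meta_cols) tab$alt_allele else "B",
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(t(dos), snps, sample_ids = sample_cols)
  compute_maf(g)
}

#' Write a genotype matrix as a dosage TSV
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(snp_id = g$snps$snp_id, chrom = g$snps$chrom,
                    pos = g$snps$pos, ref_allele = g$snps$ref_allele,
                    alt_allele = g$snps$alt_allele,
                    t(g$dosage), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids; `"NA"` or
#' empty cells mark missing values.
#'
#' @param path file path.
#' @param kind `"miRNA"` or `"mRNA"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1)
    stop("ragged rows in ", path, " (line ", which(nf != nf[1])[1], ")")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  feature_ids <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  cells[cells == "NA"] <- NA_character_
  suppressWarnings(vals <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], feature_ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  dimnames(vals) <- list(feature_ids, colnames(tab)[-1])
  expression_matrix(vals, kind)
}

#' Write an expression matrix as TSV
#' @param e an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(e, path) {
  stopifnot(inherits(e, "expression_matrix"))
  tab <- data.frame(feature_id = rownames(e$values), e$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation catalog
#'
#' A catalog row links a SNP to a trait or drug annotation, optionally with
#' the published risk allele and an evidence level in \{1, 2, 3\} (1 =
#' replicated large-cohort association, 3 = in-vitro/PK support only).
#'
#' @param path TSV with required columns `snp_id` and `annotation`; optional
#'   `risk_allele`, `evidence_level`, `source`.
#' @return data frame of class `catalog_table`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  catalog_table(tab)
}

#' Construct/validate a catalog table
#' @param tab data frame with `snp_id`, `annotation` and optional
#'   `risk_allele`, `evidence_level`, `source` columns.
#' @return data frame of class `catalog_table`.
#' @export
catalog_table <- function(tab) {
  req <- c("snp_id", "annotation")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("catalog lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(is.na(tab$snp_id) | tab$snp_id == ""))
    stop("catalog snp_id must be non-empty")
  for (col in c("risk_allele", "source"))
    if (!(col %in% names(tab))) tab[[col]] <- NA_character_
  tab$risk_allele[tab$risk_allele %in% ""] <- NA_character_
  if (!("evidence_level" %in% names(tab))) tab$evidence_level <- NA_integer_
  ev <- tab$evidence_level
  ev[ev %in% c("", "NA")] <- NA
  suppressWarnings(ev <- as.integer(ev))
  bad <- !is.na(ev) & !(ev %in% 1:3)
  na_unparsed <- is.na(ev) & !(is.na(tab$evidence_level) |
                                 tab$evidence_level %in% c("", "NA"))
  if (any(bad) || any(na_unparsed))
    stop("evidence_level must be 1, 2 or 3 (offending value: ",
         tab$evidence_level[which(bad | na_unparsed)[1]], ")")
  tab$evidence_level <- ev
  tab <- tab[, c("snp_id", "annotation", "risk_allele", "evidence_level", "source")]
  class(tab) <- c("catalog_table", "data.frame")
  tab
}

#' Write a catalog table as TSV
#' @param cat_tab a `catalog_table`.
#' @param path output path.
#' @export
write_catalog <- function(cat_tab, path) {
  utils::write.table(cat_tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Recompute per-SNP minor allele frequency from dosages
#'
#' The alternate-allele frequency is `sum(dosage) / (2 * n_nonmissing)`;
#' the MAF folds it onto `[0, 0.5]`. SNPs with no non-missing calls get
#' `maf = NA` and are flagged for downstream exclusion.
#'
#' @param g a [genotype_matrix()].
#' @return `g` with `snps$maf` filled in.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n_obs <- colSums(!is.na(g$dosage))
  alt <- colSums(g$dosage, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(alt, 1 - alt)
  maf[n_obs == 0] <- NA_real_
  if (any(n_obs == 0))
    warning(sum(n_obs == 0), " SNP(s) with all dosages missing; maf undefined")
  g$snps$maf <- maf
  g
}

#' Write an association-record table as TSV
#'
#' Fixed column order: `x_id`, `y_id`, `beta`, `se`, `t`, `p`, `n`, `q`.
#' Numeric columns are written at full precision so that a read-back
#' round-trips to 15 significant digits.
#'
#' @param records association-record data frame.
#' @param path output path.
#' @export
write_association_table <- function(records, path) {
  cols <- c("x_id", "y_id", "beta", "se", "t", "p", "n", "q")
  if (nrow(records) == 0) {
    records <- empty_association_table()
  } else {
    for (col in setdiff(cols, names(records))) records[[col]] <- NA_real_
    records <- records[, cols]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(records) > 0) {
    fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
    lines <- paste(records$x_id, records$y_id, fmt(records$beta),
                   fmt(records$se), fmt(records$t), fmt(records$p),
                   ifelse(is.na(records$n), "NA", as.character(records$n)),
                   fmt(records$q), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an association-record table written by [write_association_table()]
#' @param path file path.
#' @return association-record data frame.
#' @export
read_association_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(x_id = "character", y_id = "character"))
  tab
}
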