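#' Join eQTL results with an annotation catalog
#'
#' Inner join on `snp_id`, keeping SNP-miRNA records with `p < p_max`
#' (every qualifying (SNP, miRNA, annotation) triple appears exactly once).
#' The direction of effect per risk-allele copy is `sign(beta_alt)` when
#' the published risk allele is the alternate allele, the opposite sign
#' when it is the reference allele, and absent when the risk allele is
#' unknown or matches neither allele (logged).
#'
#' @param eqtls association-record data frame from [eqtl_scan()] (`x_id` =
#'   SNP id).
#' @param catalog a `catalog_table`.
#' @param snps SNP metadata data frame with `snp_id`, `ref_allele`,
#'   `alt_allele` (e.g. `g$snps`).
#' @param p_max association threshold for the join (default 1e-4).
#' @return data frame with columns `snp_id`, `annotation`,
#'   `evidence_level`, `mirna_id`, `p`, `beta_alt`, `direction_risk`.
#' @export
annotate_eqtls <- function(eqtls, catalog, snps, p_max = 1e-4) {
  stopifnot(inherits(catalog, "catalog_table"))
  hits <- eqtls[!is.na(eqtls$p) & eqtls$p < p_max, , drop = FALSE]
  joined <- merge(
    data.frame(snp_id = hits$x_id, mirna_id = hits$y_id, p = hits$p,
               beta_alt = hits$beta, stringsAsFactors = FALSE),
    catalog[, c("snp_id", "annotation", "risk_allele", "evidence_level")],
    by = "snp_id")
  if (nrow(joined) == 0)
    return(data.frame(snp_id = character(0), annotation = character(0),
                      evidence_level = integer(0), mirna_id = character(0),
                      p = numeric(0), beta_alt = numeric(0),
                      direction_risk = numeric(0), stringsAsFactors = FALSE))
  idx <- match(joined$snp_id, snps$snp_id)
  ref <- snps$ref_allele[idx]
  alt <- snps$alt_allele[idx]
  dir <- rep(NA_real_, nrow(joined))
  is_alt <- !is.na(joined$risk_allele) & joined$risk_allele == alt
  is_ref <- !is.na(joined$risk_allele) & joined$risk_allele == ref
  dir[is_alt] <- sign(joined$beta_alt[is_alt])
  dir[is_ref] <- -sign(joined$beta_alt[is_ref])
  unmatched <- !is.na(joined$risk_allele) & !is_alt & !is_ref
  if (any(unmatched))
    message("annotate_eqtls: ", sum(unmatched),
            " record(s) with risk allele matching neither allele; direction absent")
  out <- data.frame(snp_id = joined$snp_id, annotation = joined$annotation,
                    evidence_level = joined$evidence_level,
                    mirna_id = joined$mirna_id, p = joined$p,
                    beta_alt = joined$beta_alt, direction_risk = dir,
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Pharmacogenetic catalog enrichment screen
#'
#' Treats the catalog SNPs (optionally restricted by evidence level) as the
#' query, SNPs with any miRNA association at `p < p_max` as the target, and
#' delegates to [overlap_enrichment()] over MAF-matched null sets. Also
#' returns the annotated association table for the qualifying SNPs.
#'
#' @param eqtls association-record data frame from [eqtl_scan()].
#' @param catalog a `catalog_table` carrying evidence levels.
#' @param snps SNP metadata with `snp_id`, `maf`, `ref_allele`,
#'   `alt_allele` (the matching pool).
#' @param p_max miRNA-association threshold (default 1e-3).
#' @param levels optional subset of evidence levels, e.g. `c(1, 2)`.
#' @param B number of null sets (default 1000).
#' @param bin_width MAF bin width (default 0.05).
#' @param seed integer seed.
#' @return list with `enrichment` (an `enrichment_result`) and `annotated`
#'   (the [annotate_eqtls()] table at `p_max`).
#' @export
pharmacogenetic_screen <- function(eqtls, catalog, snps, p_max = 1e-3,
                                   levels = NULL, B = 1000,
                                   bin_width = 0.05, seed = 1L) {
  stopifnot(inherits(catalog, "catalog_table"))
  if (!is.null(levels)) {
    catalog <- catalog[!is.na(catalog$evidence_level) &
                         catalog$evidence_level %in% levels, , drop = FALSE]
    if (nrow(catalog) == 0)
      stop("no catalog entries at evidence level(s) ",
           paste(levels, collapse = ", "))
    class(catalog) <- c("catalog_table", "data.frame")
  }
  query <- unique(catalog$snp_id)
  query <- query[query %in% snps$snp_id]
  if (length(query) == 0) stop("no catalog SNP present in the SNP pool")
  target <- unique(eqtls$x_id[!is.na(eqtls$p) & eqtls$p < p_max])
  nulls <- maf_matched_null_sets(query, snps, B = B, bin_width = bin_width,
                                 seed = seed)
  enr <- overlap_enrichment(query, target, nulls)
  ann <- annotate_eqtls(eqtls, catalog, snps, p_max = p_max)
  list(enrichment = enr, annotated = ann)
}
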