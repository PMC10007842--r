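# Missing-genotype filling with per-call provenance flags. A deterministic
# majority rule stands behind the imputation stage: the catalog computation
# needs filled genotypes plus flags, not phased haplotypes, and the interface
# also accepts externally imputed panels via a sidecar missingness mask.

# Canonical (sorted) genotype of one accession at one record.
canon_gt <- function(pair) sort(pair)

# The fill genotype of one site: most frequent non-missing genotype; ties
# broken toward the genotype with more reference alleles, then lowest allele
# indices. All-missing sites fall back to homozygous reference.
site_fill_value <- function(rec) {
  called <- which(!is.na(rec$gt[, 1L]))
  if (length(called) == 0L) return(c(0L, 0L))
  gts <- lapply(called, function(a) canon_gt(rec$gt[a, ]))
  keys <- vapply(gts, paste, "", collapse = "/")
  tab <- table(keys)
  cand <- names(tab)[tab == max(tab)]
  pairs <- lapply(strsplit(cand, "/", fixed = TRUE), as.integer)
  n_ref <- vapply(pairs, function(p) sum(p == 0L), 0L)
  ord <- order(-n_ref,
               vapply(pairs, `[[`, 0L, 1L),
               vapply(pairs, `[[`, 0L, 2L))
  pairs[[ord[1L]]]
}

#' Fill missing genotypes with the site-majority rule
#'
#' Every missing call is replaced by its site's most frequent non-missing
#' genotype; ties break toward the genotype containing more reference alleles,
#' then lowest allele indices. A site with no called genotypes is filled
#' homozygous-reference with a warning. Non-missing genotypes are never
#' changed, and the original missingness flags are preserved on the records so
#' imputation provenance flows through to catalog cells.
#'
#' @param records Variant records (see [read_vcf_panel()]).
#' @return A list with `records` (fully called), `imputed_flags` (list of
#'   logical vectors, one per record, `TRUE` exactly where the input was
#'   missing), `site_fill` (list of the integer genotype used per site) and
#'   `n_imputed` (total filled calls).
#' @export
impute_major <- function(records) {
  if (length(records) > 0L && nrow(records[[1L]]$gt) == 0L) {
    stop("impute_major: no accessions")
  }
  fills <- vector("list", length(records))
  flags <- vector("list", length(records))
  n_imputed <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    fill <- site_fill_value(rec)
    if (all(is.na(rec$gt[, 1L]))) {
      warning("all genotypes missing at ", rec$chrom, ":", rec$pos,
              "; filled homozygous reference")
    }
    miss <- which(is.na(rec$gt[, 1L]))
    for (a in miss) rec$gt[a, ] <- fill
    fills[[i]] <- fill
    flags[[i]] <- rec$missing
    n_imputed <- n_imputed + length(miss)
    records[[i]] <- rec
  }
  list(records = records, imputed_flags = flags, site_fill = fills,
       n_imputed = n_imputed)
}

#' Gene-level imputation flag for one accession
#'
#' `"+"` when at least one of the accession's catalog cells in the gene was
#' imputed, `"-"` otherwise (including genes with no modifying positions).
#'
#' @param cell_imputed Logical vector of per-cell imputation flags for one
#'   (accession, gene).
#' @return `"+"` or `"-"`.
#' @export
gene_imputation_flag <- function(cell_imputed) {
  if (length(cell_imputed) > 0L && any(cell_imputed)) "+" else "-"
}

#' Apply a sidecar missingness mask to a pre-imputed panel
#'
#' When consuming an externally imputed VCF (no `./.` left), original
#' missingness can be supplied as a tab-delimited mask with columns
#' `accession`, `chrom`, `pos`; matching calls get their imputation flag set
#' so provenance still reaches the catalog.
#'
#' @param panel A panel from [read_vcf_panel()].
#' @param mask_path Path to the mask TSV.
#' @return The panel with updated `missing` flags.
#' @export
apply_missingness_mask <- function(panel, mask_path) {
  mask <- utils::read.delim(mask_path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
  need <- c("accession", "chrom", "pos")
  if (!all(need %in% names(mask))) {
    stop("mask format error: columns must include ",
         paste(need, collapse = ", "))
  }
  keys <- paste(mask$accession, mask$chrom, mask$pos, sep = "\r")
  for (i in seq_along(panel$records)) {
    rec <- panel$records[[i]]
    rk <- paste(panel$accessions, rec$chrom, rec$pos, sep = "\r")
    hit <- rk %in% keys
    panel$records[[i]]$missing <- rec$missing | hit
  }
  panel
}
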