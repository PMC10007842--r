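# Library equivalents of the catalog's two search modes and the per-allele
# accession detail view, with machine-readable output.

#' Search the catalog by gene ids
#'
#' One result per known gene id: the allele frequency table (optionally
#' recomputed over a categorical subset of the panel) plus the catalog rows
#' grouped by allele. Unknown ids are reported with a warning, not fatal; an
#' all-unknown query returns an empty list.
#'
#' @param catalog An `allele_catalog` from [build_catalog()].
#' @param gene_ids Non-empty character vector of gene ids.
#' @param category_filter Optional named list: metadata column -> kept values.
#'   Accessions are restricted before frequency computation.
#' @return A list of per-gene results, each with `gene_id`, `positions`
#'   (labels), `frequency` (data.frame) and `rows` (catalog rows with a
#'   leading `Allele` column).
#' @export
search_by_gene_ids <- function(catalog, gene_ids, category_filter = NULL) {
  if (length(gene_ids) == 0L) stop("gene_ids must be non-empty")
  known <- gene_ids[gene_ids %in% names(catalog$alleles)]
  unknown <- setdiff(gene_ids, known)
  if (length(unknown) > 0L) {
    warning("unknown gene id(s): ", paste(unknown, collapse = ", "))
  }
  subset <- filter_accessions(catalog, category_filter)
  out <- lapply(known, function(gid) {
    alleles <- catalog$alleles[[gid]]
    pos_df <- attr(alleles, "positions")
    freq <- build_frequency_table(alleles, catalog$metadata,
                                  catalog$category_spec,
                                  accession_subset = subset)
    rows <- catalog_rows(catalog, gid, accessions = subset)
    if (nrow(rows) > 0L) {
      allele_of <- allele_index_of(alleles, rows[[1L]])
      rows <- cbind(Allele = as.character(allele_of), rows,
                    stringsAsFactors = FALSE)
    } else {
      rows <- cbind(Allele = character(0), rows, stringsAsFactors = FALSE)
    }
    list(gene_id = gid, positions = pos_df$label, frequency = freq,
         rows = rows)
  })
  names(out) <- known
  out
}

# Accessions passing a named-list category filter; NULL means no restriction.
filter_accessions <- function(catalog, category_filter) {
  if (is.null(category_filter) || length(category_filter) == 0L) return(NULL)
  meta <- catalog$metadata
  keep <- catalog$accessions
  for (col in names(category_filter)) {
    if (!col %in% names(meta)) {
      stop("unknown metadata column in category filter: ", col)
    }
    vals <- as.character(category_filter[[col]])
    ok <- vapply(keep, function(a) {
      row <- metadata_row(meta, a)
      !is.null(row) && row[[col]] %in% vals
    }, TRUE, USE.NAMES = FALSE)
    keep <- keep[ok]
  }
  keep
}

# Map accession -> 1-based allele index (Total-descending order).
allele_index_of <- function(alleles, accs) {
  idx <- integer(length(accs))
  for (al in alleles) idx[accs %in% al$carriers] <- al$index
  idx
}

#' Genotype a list of accessions for one gene
#'
#' The accession-oriented search: one catalog row per requested accession
#' present in the panel, in request order, without frequency information.
#' Unknown accessions are reported with a warning and omitted.
#'
#' @param catalog An `allele_catalog`.
#' @param accessions Character vector of accession ids.
#' @param gene_id A single known gene id (unknown ids are an error).
#' @return A data.frame of catalog rows in the dialect of [catalog_rows()].
#' @export
search_by_accessions_and_gene <- function(catalog, accessions, gene_id) {
  if (!gene_id %in% names(catalog$alleles)) {
    stop("unknown gene id: ", gene_id)
  }
  known <- accessions[accessions %in% catalog$accessions]
  unknown <- setdiff(accessions, known)
  if (length(unknown) > 0L) {
    warning("accession(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  rows <- catalog_rows(catalog, gene_id, accessions = known)
  if (nrow(rows) > 0L) {
    rows <- rows[order(match(rows[[1L]], known)), , drop = FALSE]
    rownames(rows) <- NULL
  }
  rows
}

#' Detail view for the carriers of one allele in one category
#'
#' The equivalent of selecting one frequency cell of the summary table: the
#' meta-information and per-position genotype cells (with `|+` imputation
#' marks and the gene-level `"+"`/`"-"` flag) of the carriers of that allele
#' within one category value, or of all carriers for `"Total"`.
#'
#' @param catalog An `allele_catalog`.
#' @param gene_id A known gene id.
#' @param allele_index 1-based allele index in Total-descending order.
#' @param category_value A category value from the panel's category
#'   specification, a flag column name, or `"Total"`.
#' @return A data.frame of catalog rows (zero rows for a zero-count cell).
#' @export
accession_detail <- function(catalog, gene_id, allele_index,
                             category_value = "Total") {
  if (!gene_id %in% names(catalog$alleles)) {
    stop("unknown gene id: ", gene_id)
  }
  alleles <- catalog$alleles[[gene_id]]
  if (allele_index < 1L || allele_index > length(alleles)) {
    stop("allele index out of range: ", allele_index)
  }
  spec <- catalog$category_spec
  ok_values <- c("Total", spec$category_values, spec$flag_columns)
  if (!category_value %in% ok_values) {
    stop("unknown category value: ", category_value)
  }
  carriers <- alleles[[allele_index]]$carriers
  if (category_value != "Total") {
    meta <- catalog$metadata
    if (category_value %in% spec$flag_columns) {
      carriers <- carriers[vapply(carriers, function(a) {
        accession_flag(meta, spec, a, category_value)
      }, TRUE)]
    } else {
      carriers <- carriers[vapply(carriers, function(a) {
        identical(accession_category(meta, spec, a), category_value)
      }, TRUE)]
    }
  }
  rows <- catalog_rows(catalog, gene_id, accessions = carriers)
  rows
}

#' Dump the panel's accession meta-information
#'
#' @param catalog An `allele_catalog`.
#' @return A data.frame: one row per panel accession (uncategorized accessions
#'   included with empty metadata columns).
#' @export
dump_metadata <- function(catalog) {
  meta <- catalog$metadata
  cols <- names(meta)
  rows <- lapply(catalog$accessions, function(a) {
    row <- metadata_row(meta, a)
    vals <- vapply(cols[-1L], function(cn) {
      if (is.null(row)) "" else row[[cn]]
    }, "")
    c(stats::setNames(a, cols[1L]), vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  rownames(df) <- NULL
  df
}
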