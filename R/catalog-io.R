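#' Format / parse one allele-catalog cell
#'
#' Cell grammar: `STATE("|"EFFECT_TERM"|"AA_NOTATION)?("|+")?`. The genotype
#' state alone marks a reference call; an alternate call appends the predicted
#' effect term and amino-acid-change notation (the notation may be empty for
#' effects that do not touch the protein sequence, e.g. splice-core changes);
#' a trailing `|+` marks a genotype that was originally missing and imputed.
#'
#' @param state Genotype state string (e.g. `"C"`, `"G"`, `"A/G"`).
#' @param effect_term Effect term, or `""` for reference calls.
#' @param aa Amino-acid-change notation, or `""`.
#' @param imputed Logical; was this genotype imputed?
#' @return [format_catalog_cell()] returns the cell string;
#'   [parse_catalog_cell()] returns a list with `state`, `effect_term`, `aa`,
#'   `imputed`.
#' @export
format_catalog_cell <- function(state, effect_term = "", aa = "",
                                imputed = FALSE) {
  cell <- state
  if (nzchar(effect_term)) cell <- paste(cell, effect_term, aa, sep = "|")
  if (imputed) cell <- paste0(cell, "|+")
  cell
}

#' @rdname format_catalog_cell
#' @param cell A cell string.
#' @export
parse_catalog_cell <- function(cell) {
  n_sep <- lengths(regmatches(cell, gregexpr("|", cell, fixed = TRUE)))
  parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
  parts <- c(parts, rep("", n_sep + 1L - length(parts)))  # trailing empties
  imputed <- length(parts) > 1L && parts[length(parts)] == "+"
  if (imputed) parts <- parts[-length(parts)]
  if (!length(parts) %in% c(1L, 3L)) {
    stop("catalog cell format error: '", cell, "'")
  }
  list(state = parts[1L],
       effect_term = if (length(parts) == 3L) parts[2L] else "",
       aa = if (length(parts) == 3L) parts[3L] else "",
       imputed = imputed)
}

#' Write / read the tab-delimited Allele Catalog dialect
#'
#' One file holds the rows of a single gene: header columns are the accession
#' identifier, the meta-information columns, `Gene`, `Imputation`, then one
#' column per modifying variant position labelled `Chrom:Pos`. Cells follow
#' the grammar of [format_catalog_cell()]. A write followed by a read is
#' byte-identical.
#'
#' @param rows Data.frame of catalog rows (all character columns).
#' @param path File path.
#' @return [read_allele_catalog()] returns the rows data.frame;
#'   [write_allele_catalog()] returns `path` invisibly.
#' @export
write_allele_catalog <- function(rows, path) {
  lines <- c(paste(names(rows), collapse = "\t"),
             if (nrow(rows) > 0L) {
               do.call(paste, c(lapply(rows, as.character), sep = "\t"))
             })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_allele_catalog
#' @export
read_allele_catalog <- function(path) {
  if (!file.exists(path)) stop("allele catalog file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("allele catalog format error: empty file")
  split_keep <- function(line) {
    n <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    c(f, rep("", n + 1L - length(f)))  # keep trailing empty fields
  }
  header <- split_keep(lines[1L])
  body <- lapply(lines[-1L], split_keep)
  bad <- which(lengths(body) != length(header))
  if (length(bad) > 0L) {
    stop("allele catalog format error: ragged row at line ", bad[1L] + 1L)
  }
  mat <- if (length(body) > 0L) do.call(rbind, body) else {
    matrix(character(0), ncol = length(header))
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  rownames(df) <- NULL
  df
}
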