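#' Declare the categorical structure of a panel's meta-information
#'
#' Which meta-information columns form the primary frequency-table partition
#' (e.g. Improvement Status with values G. soja / Landrace / Elite), which are
#' independent flag columns (e.g. Cultivar), and which are free-form details
#' (Maturity Group, Country, State, ...) differs between species panels, so it
#' is declared per panel rather than hard-coded.
#'
#' @param category_column Name of the metadata column holding the primary
#'   partition category.
#' @param category_values Ordered character vector of category values; these
#'   become the frequency-table columns, in this order.
#' @param flag_columns Character vector of additional flag columns counted
#'   independently of the partition.
#' @param flag_true_values Values of a flag column treated as "flag set".
#' @return An object of class `category_spec`.
#' @export
category_spec <- function(category_column,
                          category_values,
                          flag_columns = character(0),
                          flag_true_values = c("Yes", "Y", "1", "TRUE", "True")) {
  stopifnot(length(category_column) <= 1L)
  structure(
    list(category_column = category_column,
         category_values = as.character(category_values),
         flag_columns = as.character(flag_columns),
         flag_true_values = as.character(flag_true_values)),
    class = "category_spec"
  )
}

#' An empty category specification (Total column only)
#' @return A `category_spec` with no category column and no flags.
#' @export
empty_category_spec <- function() {
  structure(
    list(category_column = character(0), category_values = character(0),
         flag_columns = character(0), flag_true_values = character(0)),
    class = "category_spec"
  )
}

#' Read / write a category specification as JSON
#'
#' @param path Path to a JSON file with fields `category_column`,
#'   `category_values`, and optionally `flag_columns`, `flag_true_values`.
#' @return [read_category_spec()] returns a `category_spec`;
#'   [write_category_spec()] returns `path` invisibly.
#' @export
read_category_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$category_column) || length(x$category_column) == 0L) {
    return(empty_category_spec())
  }
  category_spec(
    category_column = x$category_column,
    category_values = x$category_values,
    flag_columns = x$flag_columns %||% character(0),
    flag_true_values = x$flag_true_values %||% c("Yes", "Y", "1", "TRUE", "True")
  )
}

#' @rdname read_category_spec
#' @param spec A `category_spec`.
#' @export
write_category_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read an accession meta-information table
#'
#' Tab-delimited with a header row; the first column identifies the accession
#' (whatever its header is called). All values are kept as character; missing
#' values are empty strings. Accessions present in the VCF but absent from
#' this table are permitted and treated as uncategorized downstream (counted
#' only in the Total column).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of character columns with attribute
#'   `accession_column` naming the first column.
#' @export
read_panel_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (ncol(df) < 1L) stop("metadata format error: no columns")
  acc <- df[[1L]]
  if (anyDuplicated(acc)) {
    stop("metadata format error: duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  attr(df, "accession_column") <- names(df)[1L]
  df
}

#' Write an accession meta-information table
#' @param metadata A data.frame as returned by [read_panel_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Look up one accession's metadata row; NULL when uncategorized/absent.
metadata_row <- function(metadata, accession) {
  i <- match(accession, metadata[[1L]])
  if (is.na(i)) NULL else metadata[i, , drop = FALSE]
}

# The category value of an accession, or NA when absent/uncategorized.
accession_category <- function(metadata, spec, accession) {
  if (length(spec$category_column) == 0L) return(NA_character_)
  row <- metadata_row(metadata, accession)
  if (is.null(row)) return(NA_character_)
  val <- row[[spec$category_column]]
  if (val %in% spec$category_values) val else NA_character_
}

# TRUE when the accession has a given flag column set.
accession_flag <- function(metadata, spec, accession, flag) {
  row <- metadata_row(metadata, accession)
  if (is.null(row) || !flag %in% names(row)) return(FALSE)
  row[[flag]] %in% spec$flag_true_values
}
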