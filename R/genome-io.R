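#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into an in-memory genome representation:
#' a named character vector of uppercase nucleotide strings, one element per
#' chromosome, in file order. Record names are truncated at the first
#' whitespace, as is conventional for sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of class `genome_sequence`; names are
#'   chromosome identifiers, values uppercase sequences over A, C, G, T, N.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA format error: no records in ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("FASTA format error: duplicate record name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- nms
  if (any(nchar(x) == 0L)) stop("FASTA format error: empty sequence record")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("FASTA format error: sequence alphabet outside A,C,G,T,N in record(s): ",
         paste(nms[bad], collapse = ", "))
  }
  structure(x, class = "genome_sequence")
}

#' Write a genome to FASTA
#'
#' @param genome A named character vector as returned by [read_genome_fasta()].
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
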