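#' @keywords internal
"_PACKAGE"

# Nucleotide complement over the A,C,G,T,N alphabet.
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of a nucleotide string
#'
#' @param x A character scalar over the alphabet A, C, G, T, N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a nucleotide string into codons (complete triplets only).
codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate codons with the standard genetic code; any codon that is not a
# plain A/C/G/T triplet (e.g. contains N) becomes "X".
codon_aas <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Trim the shared prefix, then the shared suffix, of a REF/ALT pair and
# return the changed genomic interval in reference coordinates.
# ref_core == "" means a pure insertion between g_start - 1 and g_start.
trim_ref_alt <- function(pos, ref, alt) {
  p <- 0L
  nmin <- min(nchar(ref), nchar(alt))
  while (p < nmin && substr(ref, p + 1L, p + 1L) == substr(alt, p + 1L, p + 1L)) {
    p <- p + 1L
  }
  r <- substr(ref, p + 1L, nchar(ref))
  a <- substr(alt, p + 1L, nchar(alt))
  s <- 0L
  nmin <- min(nchar(r), nchar(a))
  while (s < nmin &&
         substr(r, nchar(r) - s, nchar(r) - s) == substr(a, nchar(a) - s, nchar(a) - s)) {
    s <- s + 1L
  }
  r <- substr(r, 1L, nchar(r) - s)
  a <- substr(a, 1L, nchar(a) - s)
  list(
    ref_core = r,
    alt_core = a,
    g_start = pos + p,
    g_end = pos + p + nchar(r) - 1L
  )
}

# Position label used for catalog columns.
position_label <- function(chrom, pos) paste0(chrom, ":", pos)

# Site key used to index variant records.
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

`%||%` <- function(a, b) if (is.null(a)) b else a
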