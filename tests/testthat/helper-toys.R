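# Hand-built micro-fixtures used across test files.

# chr1: 10 bp of C padding, then the 15 bp CDS ATG ACT GGG TTG TAA, then
# padding. Coding protein: MTGL*.
toy_genome <- function() {
  structure(
    c(chr1 = paste0(strrep("C", 10), "ATGACTGGGTTGTAA", strrep("G", 15))),
    class = "genome_sequence")
}

toy_gene <- function(strand = "+") {
  gene_model("toy1", "chr1", 11L, 25L, strand, list(
    list(transcript_id = "toy1.t1",
         exons = data.frame(start = 11L, end = 25L),
         cds = data.frame(start = 11L, end = 25L, phase = 0L))))
}

# Two-exon plus-strand gene: CDS split ATGACTGG | GTTGTAA with a 20 bp intron.
toy_split_genome <- function() {
  structure(
    c(chr1 = paste0(strrep("C", 10), "ATGACTGG",
                    "GTAAGTTTTTTTTTTTTCAG",  # intron, 20 bp
                    "GTTGTAA", strrep("G", 15))),
    class = "genome_sequence")
}

toy_split_gene <- function() {
  gene_model("toy2", "chr1", 11L, 45L, "+", list(
    list(transcript_id = "toy2.t1",
         exons = data.frame(start = c(11L, 39L), end = c(18L, 45L)),
         cds = data.frame(start = c(11L, 39L), end = c(18L, 45L),
                          phase = c(0L, 1L)))))
}

# A plus-strand single-exon gene built from an explicit codon vector, placed
# at `offset` bases into a padded chromosome.
gene_from_codons <- function(codons, offset = 50L, gene_id = "g1",
                             strand = "+", chrom = "chr1") {
  coding <- paste(codons, collapse = "")
  genomic <- if (strand == "+") coding else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
  }
  seqstr <- paste0(strrep("T", offset), genomic, strrep("T", 30))
  genome <- structure(stats::setNames(seqstr, chrom),
                      class = "genome_sequence")
  start <- offset + 1L
  end <- offset + nchar(coding)
  gene <- gene_model(gene_id, chrom, start, end, strand, list(
    list(transcript_id = paste0(gene_id, ".t1"),
         exons = data.frame(start = start, end = end),
         cds = data.frame(start = start, end = end, phase = 0L))))
  list(genome = genome, gene = gene, start = start, end = end)
}

# One variant record with explicit genotypes: gts is a list of integer pairs
# or NA for a missing call.
make_record <- function(chrom, pos, ref, alt, gts, info = ".") {
  n <- length(gts)
  gt <- matrix(NA_integer_, nrow = n, ncol = 2L)
  missing <- logical(n)
  for (i in seq_len(n)) {
    if (length(gts[[i]]) == 1L && is.na(gts[[i]])) {
      missing[i] <- TRUE
    } else {
      gt[i, ] <- as.integer(gts[[i]])
    }
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref,
       alt = as.character(alt), info = info, gt = gt, missing = missing)
}

# Memoized fixture builds shared across test files (keyed by seed + plan tag).
.fx_cache <- new.env(parent = emptyenv())
fixture_build <- function(seed, spec = fixture_spec(seed = seed), tag = "std") {
  key <- paste0(tag, "-", seed)
  if (!is.null(.fx_cache[[key]])) return(.fx_cache[[key]])
  fx <- generate_fixture(spec, file.path(tempdir(), paste0("fx-", key)))
  catalog <- build_catalog_from_files(
    fx$files[["fasta"]], fx$files[["gff"]], fx$files[["vcf"]],
    fx$files[["metadata"]], fx$files[["category_spec"]])
  .fx_cache[[key]] <- list(fx = fx, catalog = catalog)
  .fx_cache[[key]]
}
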