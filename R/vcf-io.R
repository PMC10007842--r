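#' Read a multi-sample VCF into variant records
#'
#' Loads a VCF 4.x file (text or bgzip) and converts each site into a variant
#' record: chromosome, 1-based position, REF, ALT alleles, the diploid
#' genotype of every accession as a pair of allele indices, and a per-accession
#' flag marking genotypes that were missing in the input (`./.` or `.|.`).
#' Phased (`|`) and unphased (`/`) separators are both accepted.
#'
#' @param path Path to a VCF file with a `GT` field in FORMAT.
#' @return A list with elements `accessions` (character vector in VCF column
#'   order) and `records` (list of variant records). Each record is a list
#'   with `chrom`, `pos`, `ref`, `alt` (character vector), `info`,
#'   `gt` (integer matrix, accessions x 2, `NA` where missing) and
#'   `missing` (logical vector, one per accession).
#' @export
read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF format error: no sample columns")
  accessions <- colnames(v@gt)[-1L]
  n_acc <- length(accessions)
  n_site <- nrow(v@fix)

  records <- vector("list", n_site)
  for (i in seq_len(n_site)) {
    fmt <- strsplit(v@gt[i, 1L], ":", fixed = TRUE)[[1L]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) {
      stop("VCF format error: missing GT in FORMAT at ",
           v@fix[i, "CHROM"], ":", v@fix[i, "POS"])
    }
    alt_field <- v@fix[i, "ALT"]
    if (is.na(alt_field) || alt_field == "" || alt_field == ".") {
      stop("VCF format error: record without ALT allele at ",
           v@fix[i, "CHROM"], ":", v@fix[i, "POS"])
    }
    alt <- strsplit(alt_field, ",", fixed = TRUE)[[1L]]

    gt <- matrix(NA_integer_, nrow = n_acc, ncol = 2L)
    missing <- logical(n_acc)
    cells <- v@gt[i, -1L]
    for (a in seq_len(n_acc)) {
      if (is.na(cells[a])) {  # vcfR renders fully missing cells as NA
        missing[a] <- TRUE
        next
      }
      gstr <- strsplit(cells[a], ":", fixed = TRUE)[[1L]][gt_idx]
      if (is.na(gstr)) {
        missing[a] <- TRUE
        next
      }
      alleles <- strsplit(gstr, "[/|]")[[1L]]
      if (length(alleles) != 2L) {
        stop("VCF format error: non-diploid genotype '", gstr, "' at ",
             v@fix[i, "CHROM"], ":", v@fix[i, "POS"])
      }
      if (any(alleles == ".")) {
        missing[a] <- TRUE
      } else {
        idx <- as.integer(alleles)
        if (anyNA(idx) || any(idx < 0L) || any(idx > length(alt))) {
          stop("VCF format error: allele index out of range in '", gstr,
               "' at ", v@fix[i, "CHROM"], ":", v@fix[i, "POS"])
        }
        gt[a, ] <- idx
      }
    }
    records[[i]] <- list(
      chrom = v@fix[i, "CHROM"],
      pos = as.integer(v@fix[i, "POS"]),
      ref = v@fix[i, "REF"],
      alt = alt,
      info = if (is.na(v@fix[i, "INFO"])) "." else v@fix[i, "INFO"],
      gt = gt,
      missing = missing
    )
  }
  list(accessions = accessions, records = records)
}

#' Drop records carrying symbolic ALT alleles
#'
#' Some variant panels encode structural indels with symbolic ALT tokens such
#' as `<INS>` and `<DEL>` instead of the actual nucleotide sequence; such
#' sites cannot be annotated at the sequence level and are removed. The whole
#' record is dropped when any of its ALT alleles is symbolic.
#'
#' @param records List of variant records from [read_vcf_panel()].
#' @return A list with `records` (kept records, unchanged) and `dropped`
#'   (number of records removed).
#' @export
filter_symbolic_alts <- function(records) {
  symbolic <- vapply(records, function(r) any(grepl("^<.+>$", r$alt)), TRUE)
  list(records = records[!symbolic], dropped = sum(symbolic))
}

#' Write variant records to a VCF file
#'
#' Emits a minimal VCF 4.2 with a `GT`-only FORMAT, suitable for re-reading
#' with [read_vcf_panel()]. Missing genotypes are written as `./.`.
#'
#' @param accessions Character vector of sample names (column order).
#' @param records List of variant records (see [read_vcf_panel()]).
#' @param path Output path.
#' @param genome Optional genome (for `##contig` header lines).
#' @return `path`, invisibly.
#' @export
write_vcf_panel <- function(accessions, records, path, genome = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=allelecat",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions), collapse = "\t")
  )
  body <- vapply(records, function(r) {
    gts <- vapply(seq_along(accessions), function(a) {
      if (r$missing[a] || anyNA(r$gt[a, ])) "./."
      else paste(r$gt[a, ], collapse = "/")
    }, "")
    paste(c(r$chrom, r$pos, ".", r$ref, paste(r$alt, collapse = ","), ".",
            "PASS", r$info %||% ".", "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
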