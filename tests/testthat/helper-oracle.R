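# Brute-force effect oracle, independent of the annotator's codon
# arithmetic: apply the raw REF->ALT replacement to the chromosome, shift the
# gene's CDS coordinates, re-extract and translate both coding sequences, and
# classify from the protein difference.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

oracle_trunc <- function(aas) {
  k <- match("*", aas)
  if (!is.na(k)) aas <- aas[seq_len(k)]
  paste(aas, collapse = "")
}

# Extract the CDS of the (single) transcript given explicit segments.
oracle_extract <- function(seqstr, segs, strand) {
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    substr(seqstr, segs$start[i], segs$end[i])
  }, "")
  out <- paste(parts, collapse = "")
  if (strand == "-") oracle_revcomp(out) else out
}

# Can `b` be written as `a` with a contiguous block of k residues removed?
oracle_is_pure_deletion <- function(a, b, k) {
  if (nchar(a) - nchar(b) != k) return(FALSE)
  for (d in seq_len(nchar(b) + 1L)) {
    if (paste0(substr(a, 1L, d - 1L), substr(a, d + k, nchar(a))) == b) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_effect <- function(genome, gene, pos, ref, alt) {
  tx <- gene$transcripts[[1L]]
  seqstr <- unclass(genome)[[gene$chrom]]
  stopifnot(substr(seqstr, pos, pos + nchar(ref) - 1L) == ref)

  # splice-core windows of the introns (first/last two bases, transcript
  # direction); planted splice variants are SNVs
  exons <- tx$exons[order(tx$exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && nchar(ref) == 1L && nchar(alt) == 1L) {
    for (i in seq_len(nrow(exons) - 1L)) {
      is_ <- exons$end[i] + 1L; ie_ <- exons$start[i + 1L] - 1L
      if (ie_ < is_) next
      donor <- if (gene$strand == "+") c(is_, is_ + 1L) else c(ie_ - 1L, ie_)
      accept <- if (gene$strand == "+") c(ie_ - 1L, ie_) else c(is_, is_ + 1L)
      if (pos >= donor[1L] && pos <= donor[2L]) {
        return(list(effect_term = "splice_donor_variant", aa_notation = ""))
      }
      if (pos >= accept[1L] && pos <= accept[2L]) {
        return(list(effect_term = "splice_acceptor_variant", aa_notation = ""))
      }
    }
  }

  mut <- paste0(substr(seqstr, 1L, pos - 1L), alt,
                substr(seqstr, pos + nchar(ref), nchar(seqstr)))
  net <- nchar(alt) - nchar(ref)
  end_ref <- pos + nchar(ref) - 1L
  cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
  shifted <- cds
  for (i in seq_len(nrow(cds))) {
    if (cds$start[i] > end_ref) {
      shifted$start[i] <- cds$start[i] + net
      shifted$end[i] <- cds$end[i] + net
    } else if (cds$end[i] >= pos) {
      shifted$end[i] <- cds$end[i] + net
    }
  }
  cds_ref <- oracle_extract(seqstr, cds, gene$strand)
  cds_alt <- oracle_extract(mut, shifted, gene$strand)
  if (cds_alt == cds_ref) {
    return(list(effect_term = "non_coding_or_other", aa_notation = ""))
  }

  aas_ref <- oracle_translate(cds_ref)
  aas_alt <- oracle_translate(cds_alt)
  p_ref <- oracle_trunc(aas_ref)
  p_alt <- oracle_trunc(aas_alt)
  if (p_alt == p_ref) {
    return(list(effect_term = "synonymous_variant", aa_notation = ""))
  }
  if (substr(p_alt, 1L, 1L) != "M" && substr(p_ref, 1L, 1L) == "M") {
    return(list(effect_term = "start_lost", aa_notation = "M1?"))
  }
  d <- 1L
  nmin <- min(nchar(p_ref), nchar(p_alt))
  while (d <= nmin && substr(p_ref, d, d) == substr(p_alt, d, d)) d <- d + 1L
  res <- if (d <= nchar(p_ref)) substr(p_ref, d, d) else "X"

  if (net %% 3L != 0L) {
    return(list(effect_term = "frameshift_variant",
                aa_notation = paste0(res, d, "fs")))
  }
  if (!"*" %in% aas_alt && "*" %in% aas_ref) {
    return(list(effect_term = "stop_lost",
                aa_notation = paste0("*", match("*", aas_ref), "ext")))
  }
  stop_at <- match("*", aas_alt)
  if (!is.na(stop_at) && stop_at < length(aas_alt)) {
    return(list(effect_term = "stop_gained",
                aa_notation = paste0(res, d, "*")))
  }
  if (net < 0L) {
    term <- if (oracle_is_pure_deletion(p_ref, p_alt, -net %/% 3L)) {
      "conservative_inframe_deletion"
    } else "disruptive_inframe_deletion"
    return(list(effect_term = term, aa_notation = paste0(res, d, "del")))
  }
  if (net > 0L) {
    term <- if (oracle_is_pure_deletion(p_alt, p_ref, net %/% 3L)) {
      "conservative_inframe_insertion"
    } else "disruptive_inframe_insertion"
    return(list(effect_term = term, aa_notation = paste0(res, d, "ins")))
  }
  list(effect_term = "missense_variant",
       aa_notation = paste0(res, d, substr(p_alt, d, d)))
}
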