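# Functional-effect prediction for coding SNPs/indels and splice-core
# variants, evaluated on one primary transcript per gene.

EFFECT_TERMS <- c(
  "synonymous_variant", "missense_variant", "stop_gained", "stop_lost",
  "start_lost", "frameshift_variant",
  "conservative_inframe_insertion", "conservative_inframe_deletion",
  "disruptive_inframe_insertion", "disruptive_inframe_deletion",
  "splice_donor_variant", "splice_acceptor_variant", "non_coding_or_other"
)

NULL_TERMS <- c("stop_gained", "stop_lost", "start_lost",
                "frameshift_variant", "splice_donor_variant",
                "splice_acceptor_variant")

MODIFYING_ONLY_TERMS <- c("missense_variant",
                          "conservative_inframe_insertion",
                          "conservative_inframe_deletion",
                          "disruptive_inframe_insertion",
                          "disruptive_inframe_deletion")

#' Severity class and display color of an effect term
#'
#' Severity drives catalog membership: `null` effects are predicted to abolish
#' gene function (nonsense, frameshift, start/stop changes, splice-core);
#' `modifying` effects change the gene product without necessarily abolishing
#' it (missense, in-frame indels); `non_modifying` effects (synonymous,
#' non-coding) are excluded from the catalog. Display colors follow the
#' catalog's rendering convention: missense blue, conservative in-frame indels
#' orange, splice-core green, other null effects red, anything else white;
#' reference states render grey at display time.
#'
#' @param effect_term One of the supported effect terms.
#' @return A list with `severity` (`"null"`, `"modifying"` or
#'   `"non_modifying"`) and `display_color`.
#' @export
classify_severity <- function(effect_term) {
  if (!effect_term %in% EFFECT_TERMS) {
    stop("unknown effect term: ", effect_term)
  }
  severity <- if (effect_term %in% NULL_TERMS) "null"
  else if (effect_term %in% MODIFYING_ONLY_TERMS) "modifying"
  else "non_modifying"
  display_color <-
    if (effect_term == "missense_variant") "blue"
    else if (effect_term %in% c("conservative_inframe_insertion",
                                "conservative_inframe_deletion")) "orange"
    else if (effect_term %in% c("splice_donor_variant",
                                "splice_acceptor_variant")) "green"
    else if (effect_term %in% NULL_TERMS) "red"
    else "white"
  list(severity = severity, display_color = display_color)
}

#' Choose the primary transcript of a gene
#'
#' Effects are reported at gene level on one representative transcript: the
#' transcript with the longest total CDS, ties broken by lexicographically
#' smallest transcript id.
#'
#' @param gene A [gene_model()].
#' @return The transcript id.
#' @export
primary_transcript <- function(gene) {
  lens <- vapply(gene$transcripts, cds_length, 0L)
  lens <- lens[lens > 0L]
  if (length(lens) == 0L) {
    stop("no coding transcript in gene ", gene$gene_id)
  }
  ids <- names(lens)
  ids[order(-lens, ids)][1L]
}

#' Extract the coding sequence of a transcript
#'
#' CDS segments are concatenated in transcription order and
#' reverse-complemented for minus-strand genes.
#'
#' @param genome A genome from [read_genome_fasta()].
#' @param gene A [gene_model()].
#' @param transcript_id Transcript id; defaults to [primary_transcript()].
#' @return The coding sequence, 5' to 3' of the transcript.
#' @export
extract_cds <- function(genome, gene, transcript_id = NULL) {
  ctx <- gene_context(genome, gene, transcript_id)
  ctx$cds
}

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon, rendered
#' `"*"`; a trailing incomplete codon is ignored; a codon containing an
#' ambiguous base translates to `"X"`.
#'
#' @param cds Coding sequence (length >= 3).
#' @return The protein string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3L) stop("coding sequence shorter than one codon")
  aa <- codon_aas(codon_split(cds))
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at)]
  paste(aa, collapse = "")
}

# Cached per-gene annotation context: primary transcript, transcript-order
# map of CDS genomic positions, reference CDS and protein, splice-core
# windows (first/last two bases of each intron of the primary transcript).
gene_context <- function(genome, gene, transcript_id = NULL) {
  if (is.null(transcript_id)) transcript_id <- primary_transcript(gene)
  tx <- gene$transcripts[[transcript_id]]
  if (is.null(tx)) stop("unknown transcript ", transcript_id,
                        " in gene ", gene$gene_id)
  if (nrow(tx$cds) == 0L) stop("transcript ", transcript_id, " has no CDS")
  chrom_seq <- unclass(genome)[[gene$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", gene$chrom, " not in genome")
  if (max(tx$cds$end) > nchar(chrom_seq)) {
    stop("CDS segment outside chromosome bounds for gene ", gene$gene_id)
  }
  gpos <- unlist(Map(seq.int, tx$cds$start, tx$cds$end), use.names = FALSE)
  tx2g <- if (gene$strand == "+") gpos else rev(gpos)
  bases <- substring(chrom_seq, tx2g, tx2g)
  if (gene$strand == "-") bases <- comp_base(bases)
  cds <- paste(bases, collapse = "")
  prot_full <- codon_aas(codon_split(cds))

  # Introns of the primary transcript, from its exon segments.
  exons <- tx$exons
  windows <- NULL
  if (nrow(exons) > 1L) {
    is_ <- exons$end[-nrow(exons)] + 1L
    ie_ <- exons$start[-1L] - 1L
    keep <- ie_ >= is_
    is_ <- is_[keep]; ie_ <- ie_[keep]
    if (length(is_) > 0L) {
      lo2 <- pmin(is_ + 1L, ie_)
      hi2 <- pmax(ie_ - 1L, is_)
      if (gene$strand == "+") {
        windows <- data.frame(
          kind = rep(c("splice_donor_variant", "splice_acceptor_variant"),
                     each = length(is_)),
          start = c(is_, hi2), end = c(lo2, ie_))
      } else {
        windows <- data.frame(
          kind = rep(c("splice_acceptor_variant", "splice_donor_variant"),
                     each = length(is_)),
          start = c(is_, hi2), end = c(lo2, ie_))
      }
    }
  }
  list(gene_id = gene$gene_id, transcript_id = transcript_id,
       strand = gene$strand, chrom = gene$chrom,
       tx2g = tx2g, L = length(tx2g), cds = cds, prot_full = prot_full,
       splice_windows = windows)
}

# Build an effect call with derived severity/color.
effect_call <- function(gene_id, transcript_id, effect_term, aa_notation) {
  cls <- classify_severity(effect_term)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         effect_term = effect_term, aa_notation = aa_notation,
         severity = cls$severity, display_color = cls$display_color),
    class = "effect_call"
  )
}

#' @export
print.effect_call <- function(x, ...) {
  cat(sprintf("<effect_call> %s on %s (%s): %s %s [%s]\n",
              x$effect_term, x$gene_id, x$transcript_id,
              x$aa_notation, x$severity, x$display_color))
  invisible(x)
}

#' Predict the functional effect of one variant allele on a gene
#'
#' The effect is computed against the gene's primary transcript. Splice-core
#' windows (first and last two bases of each intron) are checked first; a
#' variant whose changed interval overlaps a CDS segment is then classified by
#' codon arithmetic: an SNV by comparing the reference and alternate codon, an
#' indel as a frameshift when its net length is not a multiple of three and as
#' a conservative (codon-aligned) or disruptive in-frame indel otherwise, with
#' start-loss, premature-stop and stop-loss checks applied to the altered
#' coding sequence. Anything outside CDS and splice cores is
#' `non_coding_or_other`.
#'
#' @param variant A variant record (see [read_vcf_panel()]).
#' @param alt_index Index into `variant$alt` (1-based).
#' @param gene A [gene_model()].
#' @param genome A genome from [read_genome_fasta()].
#' @param ctx Optional pre-computed [gene_context()] (internal cache).
#' @return An `effect_call` with `effect_term`, `aa_notation`, `severity` and
#'   `display_color`.
#' @export
annotate_variant <- function(variant, alt_index, gene, genome, ctx = NULL) {
  if (alt_index < 1L || alt_index > length(variant$alt)) {
    stop("alt_index out of range")
  }
  alt <- variant$alt[alt_index]
  if (grepl("^<.+>$", alt)) stop("cannot annotate symbolic ALT allele ", alt)
  if (is.null(ctx)) ctx <- gene_context(genome, gene)

  core <- trim_ref_alt(variant$pos, variant$ref, alt)
  insertion <- nchar(core$ref_core) == 0L
  # Genomic interval used for overlap tests; insertions affect the junction
  # between the two flanking bases.
  ival <- if (insertion) c(core$g_start - 1L, core$g_start)
  else c(core$g_start, core$g_end)

  mk <- function(term, aa = "") {
    effect_call(ctx$gene_id, ctx$transcript_id, term, aa)
  }
  if (nchar(core$ref_core) == 0L && nchar(core$alt_core) == 0L) {
    return(mk("non_coding_or_other"))
  }

  # 1. splice cores take precedence
  w <- ctx$splice_windows
  if (!is.null(w)) {
    hit <- which(w$start <= ival[2L] & w$end >= ival[1L])
    if (length(hit) > 0L) return(mk(w$kind[hit[1L]]))
  }

  tx2g <- ctx$tx2g
  L <- ctx$L
  cds <- ctx$cds
  prot_full <- ctx$prot_full
  minus <- ctx$strand == "-"
  res_at <- function(i) if (i >= 1L && i <= length(prot_full)) prot_full[i] else "X"

  snv <- !insertion && nchar(core$ref_core) == 1L && nchar(core$alt_core) == 1L

  # 2. locate the change in transcript coordinates
  if (snv) {
    i <- match(core$g_start, tx2g)
    if (is.na(i)) return(mk("non_coding_or_other"))
    codon_idx <- (i - 1L) %/% 3L + 1L
    off <- (i - 1L) %% 3L + 1L
    ref_codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
    alt_base <- if (minus) comp_base(core$alt_core) else core$alt_core
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt_base
    aa_ref <- codon_aas(ref_codon)
    aa_alt <- codon_aas(alt_codon)
    if (codon_idx == 1L && aa_ref == "M" && aa_alt != "M") {
      return(mk("start_lost", "M1?"))
    }
    if (aa_ref == aa_alt) return(mk("synonymous_variant"))
    if (aa_alt == "*") return(mk("stop_gained", paste0(aa_ref, codon_idx, "*")))
    if (aa_ref == "*") return(mk("stop_lost", paste0("*", codon_idx, "ext")))
    return(mk("missense_variant", paste0(aa_ref, codon_idx, aa_alt)))
  }

  if (insertion) {
    # transcript index after which the inserted sequence lands
    anchor_g <- if (minus) core$g_start else core$g_start - 1L
    other_g <- if (minus) core$g_start - 1L else core$g_start
    i_left <- match(anchor_g, tx2g)
    if (is.na(i_left) || i_left >= L || tx2g[i_left + 1L] != other_g) {
      return(mk("non_coding_or_other"))
    }
    ins <- if (minus) revcomp(core$alt_core) else core$alt_core
    alt_cds <- paste0(substr(cds, 1L, i_left), ins,
                      substr(cds, i_left + 1L, nchar(cds)))
    net <- nchar(ins)
    c1 <- i_left + 1L
    aligned <- i_left %% 3L == 0L
  } else {
    ti <- which(tx2g >= core$g_start & tx2g <= core$g_end)
    if (length(ti) == 0L) return(mk("non_coding_or_other"))
    full <- length(ti) == nchar(core$ref_core) && all(diff(ti) == 1L)
    c1 <- min(ti); c2 <- max(ti)
    repl <- if (full) {
      if (minus) revcomp(core$alt_core) else core$alt_core
    } else {
      ""  # boundary-spanning change: only the CDS-clipped deletion is applied
    }
    alt_cds <- paste0(substr(cds, 1L, c1 - 1L), repl,
                      substr(cds, c2 + 1L, nchar(cds)))
    net <- nchar(repl) - length(ti)
    aligned <- (c1 - 1L) %% 3L == 0L && c2 %% 3L == 0L
  }

  pos_res <- (c1 - 1L) %/% 3L + 1L

  # 3. start-codon disruption
  if (nchar(alt_cds) >= 3L &&
      codon_aas(substr(cds, 1L, 3L)) == "M" &&
      codon_aas(substr(alt_cds, 1L, 3L)) != "M") {
    return(mk("start_lost", "M1?"))
  }

  # 4. frameshift
  if (net %% 3L != 0L) {
    return(mk("frameshift_variant", paste0(res_at(pos_res), pos_res, "fs")))
  }

  # 5. in-frame change: inspect the altered protein
  alt_aas <- codon_aas(codon_split(alt_cds))
  n_alt <- length(alt_aas)
  alt_stop <- match("*", alt_aas)
  ref_prot <- paste(prot_full[seq_len(min(which(prot_full == "*"),
                                          length(prot_full)))], collapse = "")
  alt_prot <- paste(alt_aas[seq_len(min(alt_stop, n_alt, na.rm = TRUE))],
                    collapse = "")
  if (identical(alt_prot, ref_prot)) return(mk("synonymous_variant"))
  if (is.na(alt_stop) && "*" %in% prot_full) {
    stop_idx <- match("*", prot_full)
    return(mk("stop_lost", paste0("*", stop_idx, "ext")))
  }
  if (!is.na(alt_stop) && alt_stop < n_alt) {
    # premature stop introduced by an in-frame change
    d <- first_diff(prot_full, alt_aas)
    return(mk("stop_gained", paste0(res_at(d), d, "*")))
  }
  if (net < 0L) {
    term <- if (aligned) "conservative_inframe_deletion"
    else "disruptive_inframe_deletion"
    return(mk(term, paste0(res_at(pos_res), pos_res, "del")))
  }
  if (net > 0L) {
    term <- if (aligned) "conservative_inframe_insertion"
    else "disruptive_inframe_insertion"
    return(mk(term, paste0(res_at(pos_res), pos_res, "ins")))
  }
  # net == 0: multi-nucleotide substitution altering the protein
  d <- first_diff(prot_full, alt_aas)
  mk("missense_variant", paste0(res_at(d), d, alt_aas[d]))
}

# Index of the first differing element of two amino-acid vectors.
first_diff <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) if (a[i] != b[i]) return(i)
  n + 1L
}

#' Annotate every (variant, alt, gene) overlap in a panel
#'
#' Runs [annotate_variant()] for each concrete ALT allele of each record
#' against every gene whose span it overlaps (splice cores included, since
#' introns lie within the gene span).
#'
#' @param records Variant records (see [read_vcf_panel()]).
#' @param genes Named list of [gene_model()]s.
#' @param genome Genome from [read_genome_fasta()].
#' @return A data.frame with one row per (variant, alt, gene) pair:
#'   `chrom`, `pos`, `ref`, `alt`, `alt_index`, `gene_id`, `transcript_id`,
#'   `effect_term`, `aa_notation`, `severity`, `display_color`.
#' @export
annotate_panel <- function(records, genes, genome) {
  ctxs <- lapply(genes, function(g) gene_context(genome, g))
  out <- list()
  for (r in records) {
    for (gid in names(genes)) {
      g <- genes[[gid]]
      if (g$chrom != r$chrom) next
      span <- variant_span(r)
      if (span[2L] < g$start || span[1L] > g$end) next
      for (ai in seq_along(r$alt)) {
        if (grepl("^<.+>$", r$alt[ai])) next
        e <- annotate_variant(r, ai, g, genome, ctx = ctxs[[gid]])
        out[[length(out) + 1L]] <- data.frame(
          chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt[ai],
          alt_index = ai, gene_id = gid, transcript_id = e$transcript_id,
          effect_term = e$effect_term, aa_notation = e$aa_notation,
          severity = e$severity, display_color = e$display_color,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_index = integer(0), gene_id = character(0),
                      transcript_id = character(0), effect_term = character(0),
                      aa_notation = character(0), severity = character(0),
                      display_color = character(0)))
  }
  do.call(rbind, out)
}

# Genomic interval touched by a record's REF allele (insertions included via
# the anchor base).
variant_span <- function(r) {
  c(r$pos, r$pos + nchar(r$ref) - 1L)
}
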