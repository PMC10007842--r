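# Alternative annotation path: consume ANN-style annotation strings carried in
# the INFO field of a pre-annotated VCF, mapping the ANN effect vocabulary
# onto the internal term set.

ANN_TERM_MAP <- c(
  synonymous_variant = "synonymous_variant",
  stop_retained_variant = "synonymous_variant",
  missense_variant = "missense_variant",
  stop_gained = "stop_gained",
  stop_lost = "stop_lost",
  start_lost = "start_lost",
  initiator_codon_variant = "start_lost",
  frameshift_variant = "frameshift_variant",
  conservative_inframe_insertion = "conservative_inframe_insertion",
  conservative_inframe_deletion = "conservative_inframe_deletion",
  disruptive_inframe_insertion = "disruptive_inframe_insertion",
  disruptive_inframe_deletion = "disruptive_inframe_deletion",
  inframe_insertion = "conservative_inframe_insertion",
  inframe_deletion = "conservative_inframe_deletion",
  splice_donor_variant = "splice_donor_variant",
  splice_acceptor_variant = "splice_acceptor_variant"
)

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
            Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
            Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
            Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
            Ter = "*")

# "p.Thr27Ala" -> "T27A"; "p.Arg75fs" -> "R75fs"; "p.Trp32Ter" -> "W32*".
hgvsp_to_short <- function(x) {
  if (is.na(x) || !nzchar(x)) return("")
  x <- sub("^p\\.", "", x)
  for (code in names(AA3TO1)) {
    x <- gsub(code, AA3TO1[[code]], x, fixed = TRUE)
  }
  x
}

#' Parse ANN-style annotation entries from an INFO string
#'
#' Each ANN entry is a pipe-separated record whose leading fields are the ALT
#' allele, the effect term(s) (joined by `&`), the impact, the gene name and
#' the gene id; field 11 carries the protein-level change. Effect terms are
#' mapped onto the internal vocabulary; an entry with no mappable term becomes
#' `non_coding_or_other`.
#'
#' @param info The INFO field string of one VCF record.
#' @return A data.frame with columns `alt`, `gene_id`, `effect_term`,
#'   `aa_notation` (possibly zero rows).
#' @export
parse_ann_entries <- function(info) {
  empty <- data.frame(alt = character(0), gene_id = character(0),
                      effect_term = character(0), aa_notation = character(0))
  if (is.na(info) || !nzchar(info) || info == ".") return(empty)
  fields <- strsplit(info, ";", fixed = TRUE)[[1L]]
  ann <- fields[startsWith(fields, "ANN=")]
  if (length(ann) == 0L) return(empty)
  entries <- strsplit(sub("^ANN=", "", ann[1L]), ",", fixed = TRUE)[[1L]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1L]]
    if (length(f) < 4L) return(NULL)
    terms <- strsplit(f[2L], "&", fixed = TRUE)[[1L]]
    mapped <- ANN_TERM_MAP[terms]
    mapped <- mapped[!is.na(mapped)]
    term <- if (length(mapped) > 0L) mapped[[1L]] else "non_coding_or_other"
    gene_id <- if (length(f) >= 5L && nzchar(f[5L])) f[5L] else f[4L]
    aa <- if (length(f) >= 11L) hgvsp_to_short(f[11L]) else ""
    data.frame(alt = f[1L], gene_id = gene_id, effect_term = term,
               aa_notation = aa, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# Panel-wide annotation table from carried ANN fields (same layout as
# annotate_panel()). Entries naming genes absent from `genes` are dropped.
annotate_panel_from_ann <- function(records, genes) {
  out <- list()
  for (r in records) {
    ann <- parse_ann_entries(r$info)
    if (nrow(ann) == 0L) next
    for (k in seq_len(nrow(ann))) {
      ai <- match(ann$alt[k], r$alt)
      if (is.na(ai) || !ann$gene_id[k] %in% names(genes)) next
      cls <- classify_severity(ann$effect_term[k])
      out[[length(out) + 1L]] <- data.frame(
        chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt[ai],
        alt_index = ai, gene_id = ann$gene_id[k], transcript_id = NA_character_,
        effect_term = ann$effect_term[k], aa_notation = ann$aa_notation[k],
        severity = cls$severity, display_color = cls$display_color,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(annotate_panel(list(), list(), structure(character(0),
                                                    class = "genome_sequence")))
  }
  do.call(rbind, out)
}
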