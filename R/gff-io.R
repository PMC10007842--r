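#' Construct a gene model
#'
#' A gene model holds the coordinate frame for functional-effect calls: the
#' gene span, its strand, and per-transcript exon and CDS segments. All
#' coordinates are 1-based inclusive, matching GFF3 and VCF conventions.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive gene span, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element a list with `transcript_id`,
#'   `exons` (data.frame with `start`, `end`) and `cds` (data.frame with
#'   `start`, `end`, `phase`). Segments are stored in ascending genomic order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("gene_model: start > end for gene ", gene_id)
  if (!strand %in% c("+", "-")) stop("gene_model: strand must be '+' or '-'")
  transcripts <- lapply(transcripts, function(tx) {
    tx$exons <- tx$exons[order(tx$exons$start), , drop = FALSE]
    rownames(tx$exons) <- NULL
    if (nrow(tx$cds) > 0L) {
      tx$cds <- tx$cds[order(tx$cds$start), , drop = FALSE]
      rownames(tx$cds) <- NULL
      if (any(tx$cds$start < start | tx$cds$end > end) ||
          any(tx$exons$start < start | tx$exons$end > end)) {
        stop("gene_model: segment outside gene span for gene ", gene_id)
      }
      if (nrow(tx$cds) > 1L &&
          any(tx$cds$start[-1L] <= tx$cds$end[-nrow(tx$cds)])) {
        stop("gene_model: overlapping CDS segments in transcript ",
             tx$transcript_id)
      }
    }
    tx
  })
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(
    list(gene_id = gene_id, chrom = chrom, start = start, end = end,
         strand = strand, transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

# Total CDS length of one transcript.
cds_length <- function(tx) {
  if (nrow(tx$cds) == 0L) return(0L)
  sum(tx$cds$end - tx$cds$start + 1L)
}

#' Read gene models from a GFF3 annotation
#'
#' Parses gene, mRNA/transcript, exon and CDS rows and attaches transcripts to
#' their parent genes via the `Parent`/`ID` attributes. CDS and exon segments
#' are stored in ascending genomic order with the strand preserved.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects, keyed and ordered by gene
#'   id as encountered in the file.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, "")

  gi <- which(type == "gene")
  ti <- which(type %in% c("mRNA", "transcript"))
  if (length(gi) == 0L) stop("GFF3 format error: no gene features in ", path)

  gene_ids <- id[gi]
  tx_ids <- id[ti]
  tx_parent <- parent[ti]
  if (any(is.na(tx_parent)) || !all(tx_parent %in% gene_ids)) {
    stop("GFF3 format error: mRNA with no parent gene")
  }

  seg <- function(kind, tx) {
    k <- which(type == kind & parent == tx)
    d <- data.frame(start = GenomicRanges::start(gr)[k],
                    end = GenomicRanges::end(gr)[k])
    if (kind == "CDS") {
      ph <- gr$phase
      d$phase <- if (is.null(ph)) rep(0L, length(k)) else {
        p <- suppressWarnings(as.integer(as.character(ph[k])))
        ifelse(is.na(p), 0L, p)
      }
    }
    d[order(d$start), , drop = FALSE]
  }

  # Every CDS/exon row must name a known transcript as Parent.
  seg_rows <- which(type %in% c("CDS", "exon"))
  bad <- seg_rows[is.na(parent[seg_rows]) | !(parent[seg_rows] %in% tx_ids)]
  if (length(bad) > 0L) {
    stop("GFF3 format error: ", type[bad[1L]], " with unknown Parent '",
         parent[bad[1L]], "'")
  }

  models <- vector("list", length(gi))
  for (j in seq_along(gi)) {
    i <- gi[j]
    gid <- gene_ids[j]
    txs <- lapply(which(tx_parent == gid), function(k) {
      tid <- tx_ids[k]
      exons <- seg("exon", tid)
      cds <- seg("CDS", tid)
      if (nrow(exons) == 0L) exons <- cds[, c("start", "end"), drop = FALSE]
      list(transcript_id = tid, exons = exons, cds = cds)
    })
    models[[j]] <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      transcripts = txs
    )
  }
  names(models) <- gene_ids
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS rows with `ID`/`Parent` attributes in a
#' layout that [read_gene_models()] parses back unchanged.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tallelecat\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start, g$end, g$strand, g$gene_id))
    for (tx in g$transcripts) {
      lines <- c(lines, sprintf(
        "%s\tallelecat\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(tx$exons$start), max(tx$exons$end), g$strand,
        tx$transcript_id, g$gene_id))
      for (i in seq_len(nrow(tx$exons))) {
        lines <- c(lines, sprintf(
          "%s\tallelecat\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          g$chrom, tx$exons$start[i], tx$exons$end[i], g$strand,
          tx$transcript_id, i, tx$transcript_id))
      }
      for (i in seq_len(nrow(tx$cds))) {
        lines <- c(lines, sprintf(
          "%s\tallelecat\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
          g$chrom, tx$cds$start[i], tx$cds$end[i], g$strand,
          tx$cds$phase[i], tx$transcript_id, i, tx$transcript_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
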