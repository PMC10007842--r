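# The core computation: collate modifying variant positions into gene-level
# alleles, count carriers by category, and summarize the dataset.

#' Collate annotated variants into per-gene variant sets
#'
#' A (variant, alt) pair enters a gene's set when its predicted effect on that
#' gene has severity `null` or `modifying`; synonymous and non-coding effects
#' are excluded. A variant may appear in several overlapping genes. Each gene
#' contributes one catalog position per site, ordered by ascending position;
#' distinct ALT alleles of a multi-allelic site share the position and are
#' separated by the genotype state.
#'
#' @param effects Annotation table from [annotate_panel()].
#' @param genes Named list of [gene_model()]s.
#' @return A named list (one element per gene, in `genes` order) of
#'   data.frames with columns `chrom`, `pos`, `ref`, `alt`, `alt_index`,
#'   `effect_term`, `aa_notation`, `severity`, `display_color`, sorted by
#'   `pos` then `alt_index`.
#' @export
assign_variants_to_genes <- function(effects, genes) {
  keep <- effects[effects$severity != "non_modifying", , drop = FALSE]
  out <- lapply(names(genes), function(gid) {
    d <- keep[keep$gene_id == gid,
              c("chrom", "pos", "ref", "alt", "alt_index", "effect_term",
                "aa_notation", "severity", "display_color"), drop = FALSE]
    d <- d[order(d$pos, d$alt_index), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- names(genes)
  out
}

# Unique catalog positions (ascending) of one gene's variant set.
gene_positions <- function(gene_set) {
  u <- unique(gene_set[, c("chrom", "pos")])
  u <- u[order(u$pos), , drop = FALSE]
  rownames(u) <- NULL
  u$label <- if (nrow(u) == 0L) character(0) else {
    position_label(u$chrom, u$pos)
  }
  u
}

# Genotype state string of one accession at one record: homozygous calls
# render as the single sequence; heterozygous calls as the sequences of both
# alleles, sorted by allele index and joined with "/".
genotype_state <- function(rec, a) {
  idx <- rec$gt[a, ]
  seqs <- vapply(idx, function(k) if (k == 0L) rec$ref else rec$alt[k], "")
  if (idx[1L] == idx[2L]) seqs[1L] else paste(seqs[order(idx)], collapse = "/")
}

#' Assemble the gene-level alleles of one gene
#'
#' Each allele is the unique combination of reference or alternate genotype
#' states over the gene's modifying variant positions. Accessions with
#' identical state vectors form one allele; alleles are ordered by carrier
#' count (Total) descending, ties broken by the state vector's lexicographic
#' order. A gene with zero modifying positions yields exactly one all-reference
#' allele carrying every accession.
#'
#' @param gene_set One gene's variant set from [assign_variants_to_genes()].
#' @param records Fully imputed variant records (list).
#' @param accessions Character vector of panel accessions.
#' @return A list of alleles; each a list with `index`, `states` (one state
#'   per catalog position), `effect_term`/`aa_notation` (per position, empty
#'   for reference states), `carriers`, `total` and `imputed` (logical matrix
#'   carriers x positions). The positions data.frame is attached as attribute
#'   `positions`.
#' @export
assemble_alleles <- function(gene_set, records, accessions) {
  pos_df <- gene_positions(gene_set)
  n_pos <- nrow(pos_df)
  rec_keys <- vapply(records, function(r) site_key(r$chrom, r$pos), "")
  recs <- lapply(seq_len(n_pos), function(p) {
    i <- match(site_key(pos_df$chrom[p], pos_df$pos[p]), rec_keys)
    if (is.na(i)) stop("no variant record for catalog position ",
                       pos_df$label[p])
    records[[i]]
  })

  n_acc <- length(accessions)
  states <- matrix("", nrow = n_acc, ncol = n_pos)
  imputed <- matrix(FALSE, nrow = n_acc, ncol = n_pos)
  for (p in seq_len(n_pos)) {
    rec <- recs[[p]]
    if (anyNA(rec$gt)) {
      stop("assemble_alleles requires fully imputed genotypes (missing call ",
           "at ", pos_df$label[p], ")")
    }
    for (a in seq_len(n_acc)) {
      states[a, p] <- genotype_state(rec, a)
      imputed[a, p] <- rec$missing[a]
    }
  }

  keys <- if (n_pos == 0L) rep("", n_acc) else {
    apply(states, 1L, paste, collapse = "\x1f")
  }
  groups <- split(seq_len(n_acc), keys)
  totals <- lengths(groups)
  ord <- order(-totals, names(groups))
  groups <- groups[ord]

  alleles <- lapply(seq_along(groups), function(k) {
    members <- groups[[k]]
    st <- if (n_pos == 0L) character(0) else states[members[1L], ]
    eff <- aa <- character(n_pos)
    for (p in seq_len(n_pos)) {
      rec <- recs[[p]]
      idx <- sort(unique(rec$gt[members[1L], ]))
      idx <- idx[idx > 0L]
      rows <- gene_set[gene_set$pos == pos_df$pos[p], , drop = FALSE]
      hit <- rows[rows$alt_index %in% idx, , drop = FALSE]
      if (nrow(hit) > 0L) {
        hit <- hit[order(hit$alt_index), , drop = FALSE]
        eff[p] <- hit$effect_term[1L]
        aa[p] <- hit$aa_notation[1L]
      }
    }
    imp <- imputed[members, , drop = FALSE]
    rownames(imp) <- accessions[members]
    list(index = k, states = st, effect_term = eff, aa_notation = aa,
         carriers = accessions[members], total = length(members),
         imputed = imp)
  })
  attr(alleles, "positions") <- pos_df
  alleles
}

#' Build a per-gene allele frequency table
#'
#' One row per allele, ordered by Total descending: carrier counts per
#' category value of the panel's primary partition, independent counts for
#' each flag column, and the Total (categorized plus uncategorized carriers).
#'
#' @param alleles Alleles of one gene from [assemble_alleles()].
#' @param metadata Metadata data.frame from [read_panel_metadata()].
#' @param spec A [category_spec()].
#' @param accession_subset Optional character vector restricting the counted
#'   accessions; alleles with no remaining carrier are dropped and rows are
#'   re-ordered by the recomputed totals.
#' @return A data.frame with columns `Allele`, the category values, the flag
#'   columns and `Total`; allele state vectors are attached as attribute
#'   `states`.
#' @export
build_frequency_table <- function(alleles, metadata, spec,
                                  accession_subset = NULL) {
  if (length(spec$category_column) == 1L &&
      !spec$category_column %in% names(metadata)) {
    stop("category column '", spec$category_column,
         "' not present in metadata")
  }
  for (fc in spec$flag_columns) {
    if (!fc %in% names(metadata)) {
      stop("flag column '", fc, "' not present in metadata")
    }
  }
  rows <- lapply(alleles, function(al) {
    carriers <- al$carriers
    if (!is.null(accession_subset)) {
      carriers <- carriers[carriers %in% accession_subset]
    }
    cats <- vapply(carriers, function(a) {
      accession_category(metadata, spec, a)
    }, "", USE.NAMES = FALSE)
    counts <- vapply(spec$category_values, function(v) {
      sum(!is.na(cats) & cats == v)
    }, 0L)
    flags <- vapply(spec$flag_columns, function(fc) {
      sum(vapply(carriers, function(a) {
        accession_flag(metadata, spec, a, fc)
      }, TRUE))
    }, 0L)
    c(list(Allele = al$index), as.list(counts), as.list(flags),
      list(Total = length(carriers)))
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  states <- vapply(alleles, function(al) paste(al$states, collapse = "|"), "")
  if (!is.null(accession_subset)) {
    keep <- df$Total > 0L
    df <- df[keep, , drop = FALSE]
    states <- states[keep]
    ord <- order(-df$Total, states)
    df <- df[ord, , drop = FALSE]
    states <- states[ord]
  }
  rownames(df) <- NULL
  attr(df, "states") <- states
  df
}

#' Dataset-wide catalog summary statistics
#'
#' @param genes Named list of [gene_model()]s.
#' @param gene_sets Output of [assign_variants_to_genes()].
#' @param alleles_by_gene Named list of [assemble_alleles()] outputs.
#' @param records Pre-imputation variant records (for missingness counts).
#' @param n_accessions Number of accessions in the panel.
#' @return A list with `n_genes`, `n_genes_reference_only`,
#'   `n_genes_with_null_alleles`, `n_modifying_variants`, `n_null_variants`,
#'   `mean_positions_per_gene`, `median_positions_per_gene`,
#'   `mean_alleles_per_gene`, `median_alleles_per_gene` and
#'   `mean_missing_per_accession`. Per-gene means and medians are computed
#'   over genes with at least one modifying position.
#' @export
summarize_catalog <- function(genes, gene_sets, alleles_by_gene, records,
                              n_accessions) {
  n_pos <- vapply(gene_sets, function(d) nrow(gene_positions(d)), 0L)
  has_null <- vapply(gene_sets, function(d) any(d$severity == "null"), TRUE)
  n_alleles <- vapply(alleles_by_gene, length, 0L)

  all_pairs <- do.call(rbind, c(
    lapply(gene_sets, function(d) d[, c("chrom", "pos", "alt", "severity")]),
    list(make.row.names = FALSE)))
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
    n_mod <- 0L
    n_null <- 0L
  } else {
    key <- paste(all_pairs$chrom, all_pairs$pos, all_pairs$alt, sep = "\r")
    n_mod <- length(unique(key))
    n_null <- length(unique(key[all_pairs$severity == "null"]))
  }

  with_pos <- n_pos > 0L
  n_missing <- sum(vapply(records, function(r) sum(r$missing), 0L))

  list(
    n_genes = length(genes),
    n_genes_reference_only = sum(!with_pos),
    n_genes_with_null_alleles = sum(has_null),
    n_modifying_variants = n_mod,
    n_null_variants = n_null,
    mean_positions_per_gene = if (any(with_pos)) mean(n_pos[with_pos]) else NA_real_,
    median_positions_per_gene = if (any(with_pos)) stats::median(n_pos[with_pos]) else NA_real_,
    mean_alleles_per_gene = if (any(with_pos)) mean(n_alleles[with_pos]) else NA_real_,
    median_alleles_per_gene = if (any(with_pos)) stats::median(n_alleles[with_pos]) else NA_real_,
    mean_missing_per_accession = if (n_accessions > 0L) n_missing / n_accessions else NA_real_
  )
}

#' Build a complete allele catalog from panel inputs
#'
#' Runs the full pipeline: symbolic-ALT filtering, majority-fill imputation
#' (or a sidecar missingness mask for pre-imputed panels), functional-effect
#' annotation (internal annotator or carried ANN fields), per-gene variant
#' assignment, allele assembly, frequency tables and the dataset summary.
#'
#' @param genome Genome from [read_genome_fasta()].
#' @param genes Named list of [gene_model()]s.
#' @param panel Panel from [read_vcf_panel()].
#' @param metadata Metadata from [read_panel_metadata()].
#' @param spec A [category_spec()].
#' @param drop_symbolic Drop records with symbolic ALT alleles (default TRUE).
#' @param impute Run majority-fill imputation (default TRUE).
#' @param annotator `"internal"` for the built-in annotator, `"ann"` to use
#'   ANN-style annotation strings carried in the VCF INFO field.
#' @param mask_path Optional sidecar missingness mask (see
#'   [apply_missingness_mask()]).
#' @return An object of class `allele_catalog`.
#' @export
build_catalog <- function(genome, genes, panel, metadata, spec,
                          drop_symbolic = TRUE, impute = TRUE,
                          annotator = c("internal", "ann"),
                          mask_path = NULL) {
  annotator <- match.arg(annotator)
  counts <- list(n_records_read = length(panel$records))

  if (!is.null(mask_path)) panel <- apply_missingness_mask(panel, mask_path)

  if (drop_symbolic) {
    flt <- filter_symbolic_alts(panel$records)
    panel$records <- flt$records
    counts$n_symbolic_dropped <- flt$dropped
  } else {
    counts$n_symbolic_dropped <- 0L
  }

  pre_imputation <- panel$records
  if (impute) {
    imp <- impute_major(panel$records)
    panel$records <- imp$records
    counts$n_imputed_calls <- imp$n_imputed
  } else {
    counts$n_imputed_calls <- 0L
  }

  effects <- if (annotator == "internal") {
    annotate_panel(panel$records, genes, genome)
  } else {
    annotate_panel_from_ann(panel$records, genes)
  }
  counts$n_effects <- nrow(effects)

  gene_sets <- assign_variants_to_genes(effects, genes)
  alleles <- lapply(gene_sets, function(gs) {
    assemble_alleles(gs, panel$records, panel$accessions)
  })
  counts$n_genes_with_positions <-
    sum(vapply(gene_sets, function(d) nrow(d) > 0L, TRUE))

  freqs <- lapply(alleles, function(al) {
    build_frequency_table(al, metadata, spec)
  })
  summary <- summarize_catalog(genes, gene_sets, alleles, pre_imputation,
                               length(panel$accessions))

  structure(
    list(accessions = panel$accessions, metadata = metadata,
         category_spec = spec, genes = genes, effects = effects,
         gene_sets = gene_sets, alleles = alleles, frequencies = freqs,
         summary = summary, records = panel$records, counts = counts),
    class = "allele_catalog"
  )
}

#' @export
print.allele_catalog <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<allele_catalog> %d accessions, %d genes (%d with modifying positions)\n",
    "  modifying variants: %d (null: %d); mean alleles/gene: %s\n"),
    length(x$accessions), s$n_genes,
    s$n_genes - s$n_genes_reference_only, s$n_modifying_variants,
    s$n_null_variants,
    if (is.na(s$mean_alleles_per_gene)) "NA"
    else format(round(s$mean_alleles_per_gene, 2))))
  invisible(x)
}

#' Catalog rows of one gene in the tab-delimited dialect
#'
#' One row per accession: the accession identifier, its meta-information
#' columns (empty for uncategorized accessions), the gene id, the `"+"`/`"-"`
#' gene-level imputation flag, then one cell per modifying variant position.
#' Rows are grouped by allele (Total descending), accessions in panel order
#' within each allele.
#'
#' @param catalog An `allele_catalog`.
#' @param gene_id Gene id.
#' @param accessions Optional subset/ordering of accessions to include.
#' @return A data.frame of character columns in the catalog dialect.
#' @export
catalog_rows <- function(catalog, gene_id, accessions = NULL) {
  if (!gene_id %in% names(catalog$alleles)) {
    stop("unknown gene id: ", gene_id)
  }
  alleles <- catalog$alleles[[gene_id]]
  pos_df <- attr(alleles, "positions")
  meta <- catalog$metadata
  meta_cols <- names(meta)
  acc_col <- meta_cols[1L] %||% "Accession"

  row_for <- function(al, acc) {
    mrow <- metadata_row(meta, acc)
    meta_vals <- vapply(meta_cols[-1L], function(cn) {
      if (is.null(mrow)) "" else mrow[[cn]]
    }, "")
    imp <- al$imputed[match(acc, al$carriers), , drop = TRUE]
    cells <- vapply(seq_len(nrow(pos_df)), function(p) {
      format_catalog_cell(al$states[p], al$effect_term[p], al$aa_notation[p],
                          imputed = imp[p])
    }, "")
    c(stats::setNames(acc, acc_col), meta_vals,
      Gene = gene_id, Imputation = gene_imputation_flag(imp),
      stats::setNames(cells, pos_df$label))
  }

  rows <- list()
  for (al in alleles) {
    members <- al$carriers
    if (!is.null(accessions)) members <- members[members %in% accessions]
    members <- members[order(match(members, catalog$accessions))]
    for (acc in members) rows[[length(rows) + 1L]] <- row_for(al, acc)
  }
  header <- c(acc_col, meta_cols[-1L], "Gene", "Imputation", pos_df$label)
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = length(header)),
                        stringsAsFactors = FALSE)
    names(df) <- header
    return(df)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  rownames(df) <- NULL
  df
}
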