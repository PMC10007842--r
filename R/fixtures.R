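# Deterministic synthetic-panel generator: a toy genome with multi-exon genes
# on both strands, planted variants of every supported effect class, missing
# genotypes recoverable by the majority rule, and accessions assigned to
# categories -- together with a ground-truth manifest derived constructively
# at plant time, independent of the annotator.

#' Default planted-variant plan
#'
#' Number of variants to plant per effect class. Class names are the
#' generator's vocabulary: `missense`, `synonymous`, `stop_gained`,
#' `stop_lost`, `start_lost`, `frameshift_deletion`, `frameshift_insertion`,
#' `conservative_inframe_deletion`, `disruptive_inframe_deletion`,
#' `conservative_inframe_insertion`, `disruptive_inframe_insertion`,
#' `splice_donor`, `splice_acceptor`, `intronic`.
#'
#' @return A named integer vector.
#' @export
default_variant_plan <- function() {
  c(missense = 3L, synonymous = 2L, stop_gained = 1L, stop_lost = 1L,
    start_lost = 1L, frameshift_deletion = 2L, frameshift_insertion = 1L,
    conservative_inframe_deletion = 1L, disruptive_inframe_deletion = 1L,
    conservative_inframe_insertion = 1L, disruptive_inframe_insertion = 1L,
    splice_donor = 1L, splice_acceptor = 1L, intronic = 1L)
}

FX_CLASS_EFFECT <- c(
  missense = "missense_variant", synonymous = "synonymous_variant",
  stop_gained = "stop_gained", stop_lost = "stop_lost",
  start_lost = "start_lost", frameshift_deletion = "frameshift_variant",
  frameshift_insertion = "frameshift_variant",
  conservative_inframe_deletion = "conservative_inframe_deletion",
  disruptive_inframe_deletion = "disruptive_inframe_deletion",
  conservative_inframe_insertion = "conservative_inframe_insertion",
  disruptive_inframe_insertion = "disruptive_inframe_insertion",
  splice_donor = "splice_donor_variant",
  splice_acceptor = "splice_acceptor_variant",
  intronic = "non_coding_or_other")

#' Specify a synthetic panel fixture
#'
#' @param seed Integer seed; the same spec and seed give byte-identical files.
#' @param n_chromosomes,chrom_length Genome geometry.
#' @param n_genes Number of genes (alternating strands, 1-3 exons each; the
#'   first gene receives no modifying variants so the panel always contains a
#'   reference-only gene).
#' @param n_accessions Panel size.
#' @param category_values,category_proportions Primary-category values and
#'   their proportions of the panel (the remainder stays uncategorized, i.e.
#'   absent from the metadata file).
#' @param plan Named integer vector of planted-variant counts per class; see
#'   [default_variant_plan()].
#' @param missing_rate Fraction of genotype calls masked as `./.` (only at
#'   cells the majority rule provably restores).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_chromosomes = 2L,
                         chrom_length = 6000L,
                         n_genes = 6L,
                         n_accessions = 24L,
                         category_values = c("G. soja", "Landrace", "Elite"),
                         category_proportions = c(0.25, 0.35, 0.3),
                         plan = default_variant_plan(),
                         missing_rate = 0.03) {
  if (any(plan < 0L)) stop("fixture spec error: negative plan counts")
  if (sum(category_proportions) > 1 + 1e-9) {
    stop("fixture spec error: category proportions sum above 1")
  }
  bad <- setdiff(names(plan), names(FX_CLASS_EFFECT))
  if (length(bad) > 0L) {
    stop("fixture spec error: unknown variant class(es): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
         n_accessions = as.integer(n_accessions),
         category_values = category_values,
         category_proportions = category_proportions,
         plan = plan, missing_rate = missing_rate),
    class = "fixture_spec"
  )
}

# ---- internal construction helpers -----------------------------------------

FX_SAFE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

# SNV recipes: required reference codon, changed offset, transcript-level
# alternate base.
FX_SNV_RECIPES <- list(
  missense = c(codon = "ACT", off = "1", alt = "G"),
  synonymous = c(codon = "GGA", off = "3", alt = "G"),
  stop_gained = c(codon = "TGG", off = "2", alt = "A"),
  stop_lost = c(codon = "TAA", off = "3", alt = "C"),
  start_lost = c(codon = "ATG", off = "2", alt = "C")
)

# Codons pinned at (and around) an indel slot so that the planted REF/ALT is
# unambiguous under VCF-style prefix/suffix trimming on either strand and the
# protein-level consequence matches the intended class by construction.
FX_INDEL_PINS <- list(
  frameshift_deletion = c(`-1` = "GGC", `0` = "ACT"),
  frameshift_insertion = c(`0` = "ACT"),
  conservative_inframe_deletion = c(`-1` = "GGC", `0` = "ACT", `1` = "GGA"),
  disruptive_inframe_deletion = c(`0` = "AAA", `1` = "CCC"),
  conservative_inframe_insertion = c(`0` = "TGT", `1` = "GGA"),
  disruptive_inframe_insertion = c(`0` = "TGG")
)

# Codon span (relative to the target slot) each class needs allocated.
FX_SLOT_SPAN <- list(
  missense = c(0L, 0L), synonymous = c(0L, 0L), stop_gained = c(0L, 0L),
  frameshift_deletion = c(-1L, 0L), frameshift_insertion = c(0L, 0L),
  conservative_inframe_deletion = c(-1L, 1L),
  disruptive_inframe_deletion = c(0L, 1L),
  conservative_inframe_insertion = c(0L, 1L),
  disruptive_inframe_insertion = c(0L, 0L)
)

# Local majority-fill rule used to keep masked cells recoverable: modal
# genotype among called cells, ties toward more reference alleles, then
# lowest allele indices.
fx_fill <- function(gt_keys) {
  if (length(gt_keys) == 0L) return("0/0")
  tab <- table(gt_keys)
  cand <- names(tab)[tab == max(tab)]
  pairs <- lapply(strsplit(cand, "/", fixed = TRUE), as.integer)
  n_ref <- vapply(pairs, function(p) sum(p == 0L), 0L)
  ord <- order(-n_ref, vapply(pairs, `[[`, 0L, 1L),
               vapply(pairs, `[[`, 0L, 2L))
  cand[ord[1L]]
}

#' Generate a synthetic panel with ground truth
#'
#' Writes `genome.fasta`, `genes.gff3`, `variants.vcf`, `metadata.tsv` and
#' `category_spec.json` under `dir`, plus `manifest.json` holding the
#' ground-truth manifest. Truth (expected effect per planted variant, expected
#' per-gene allele partitions and frequency tables, expected summary, masked
#' cells) is derived at plant time by construction, not by running the
#' annotator.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `dir`, `files` (named paths) and `manifest`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  genome_chars <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms

  # -- gene geometry ---------------------------------------------------------
  cursors <- stats::setNames(rep(200L, length(chroms)), chroms)
  layouts <- list()
  for (i in seq_len(spec$n_genes)) {
    ch <- chroms[((i - 1L) %% length(chroms)) + 1L]
    strand <- if (i %% 2L == 1L) "+" else "-"
    n_exons <- ((i - 1L) %% 3L) + 1L
    n_codons <- sample(30:50, 1L)
    clen <- 3L * n_codons
    parts <- rep(clen %/% n_exons, n_exons)
    parts[n_exons] <- parts[n_exons] + clen - sum(parts)
    introns <- if (n_exons > 1L) {
      sample(60:120, n_exons - 1L, replace = TRUE)
    } else integer(0)
    gstart <- cursors[[ch]]
    span <- sum(parts) + sum(introns)
    if (gstart + span + 100L > spec$chrom_length) {
      stop("fixture spec error: chromosome too short for the gene layout")
    }
    cursors[[ch]] <- gstart + span + 200L

    exon_start <- integer(n_exons); exon_end <- integer(n_exons)
    at <- gstart
    for (e in seq_len(n_exons)) {
      exon_start[e] <- at
      exon_end[e] <- at + parts[e] - 1L
      at <- exon_end[e] + 1L + if (e < n_exons) introns[e] else 0L
    }
    gid <- sprintf("GENE%03d", i)
    gpos <- unlist(Map(seq.int, exon_start, exon_end), use.names = FALSE)
    layouts[[gid]] <- list(
      gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = ch,
      strand = strand, n_codons = n_codons,
      codons = c("ATG", sample(FX_SAFE_CODONS, n_codons - 2L, replace = TRUE),
                 "TAA"),
      exon_start = exon_start, exon_end = exon_end,
      gstart = gstart, gend = exon_end[n_exons], n_exons = n_exons,
      tx2g = if (strand == "+") gpos else rev(gpos))
  }

  # -- allocate planted variants to genes ------------------------------------
  plan <- spec$plan[spec$plan > 0L]
  multi_exon <- vapply(layouts, function(l) l$n_exons > 1L, TRUE)
  coding_hosts <- names(layouts)[-1L]  # gene 1 stays reference-only
  splice_hosts <- intersect(coding_hosts, names(layouts)[multi_exon])
  intron_hosts <- names(layouts)[multi_exon]
  if (length(coding_hosts) == 0L &&
      any(!names(plan) %in% c("synonymous", "intronic"))) {
    stop("fixture spec error: need at least two genes to plant modifying variants")
  }
  if (any(c("splice_donor", "splice_acceptor") %in% names(plan)) &&
      length(splice_hosts) == 0L) {
    stop("fixture spec error: splice variant requested but no multi-exon gene")
  }
  if ("intronic" %in% names(plan) && length(intron_hosts) == 0L) {
    stop("fixture spec error: intronic variant requested but no multi-exon gene")
  }

  plants <- list()
  used_codons <- lapply(layouts, function(l) integer(0))
  used_introns <- lapply(layouts, function(l) integer(0))
  rr <- c(coding = 0L, splice = 0L, intron = 0L)

  # Pick a target codon slot such that slot+lo .. slot+hi are interior, free,
  # at distance > 2 from other planted slots, and genomically contiguous
  # (no intron inside the touched span).
  take_slot <- function(gid, lo, hi) {
    l <- layouts[[gid]]
    excl <- unlist(lapply(used_codons[[gid]], function(u) (u - 2L):(u + 2L)))
    cand <- setdiff(3:(l$n_codons - 2L), excl)
    cand <- cand[cand + lo >= 2L & cand + hi <= l$n_codons - 1L]
    cand <- cand[vapply(cand, function(s) {
      all((s + lo:hi) %in% c(cand)) &&
        all(abs(diff(l$tx2g[(3L * (s + lo) - 2L):(3L * (s + hi))])) == 1L)
    }, TRUE)]
    if (length(cand) == 0L) return(NA_integer_)
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    used_codons[[gid]] <<- c(used_codons[[gid]], s + lo:hi)
    s
  }

  for (cls in names(plan)) {
    for (k in seq_len(plan[[cls]])) {
      if (cls %in% c("splice_donor", "splice_acceptor")) {
        placed <- FALSE
        for (try in seq_along(splice_hosts)) {
          rr[["splice"]] <- rr[["splice"]] + 1L
          gid <- splice_hosts[((rr[["splice"]] - 1L) %% length(splice_hosts)) + 1L]
          free <- setdiff(seq_len(layouts[[gid]]$n_exons - 1L),
                          used_introns[[gid]])
          if (length(free) == 0L) next
          used_introns[[gid]] <- c(used_introns[[gid]], free[1L])
          plants[[length(plants) + 1L]] <-
            list(class = cls, gene_id = gid, intron = free[1L])
          placed <- TRUE
          break
        }
        if (!placed) stop("fixture spec error: not enough introns for the splice plan")
      } else if (cls == "intronic") {
        placed <- FALSE
        for (try in seq_along(intron_hosts)) {
          rr[["intron"]] <- rr[["intron"]] + 1L
          gid <- intron_hosts[((rr[["intron"]] - 1L) %% length(intron_hosts)) + 1L]
          free <- setdiff(seq_len(layouts[[gid]]$n_exons - 1L),
                          used_introns[[gid]])
          if (length(free) == 0L) next
          used_introns[[gid]] <- c(used_introns[[gid]], free[1L])
          plants[[length(plants) + 1L]] <-
            list(class = cls, gene_id = gid, intron = free[1L])
          placed <- TRUE
          break
        }
        if (!placed) stop("fixture spec error: not enough introns for the intronic plan")
      } else {
        hosts <- if (cls %in% c("synonymous")) names(layouts) else coding_hosts
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 10L * length(hosts)) {
            stop("fixture spec error: cannot place ", cls,
                 " (plan too dense for the gene layout)")
          }
          rr[["coding"]] <- rr[["coding"]] + 1L
          gid <- hosts[((rr[["coding"]] - 1L) %% length(hosts)) + 1L]
          l <- layouts[[gid]]
          slot <- if (cls == "start_lost") {
            if (1L %in% used_codons[[gid]]) NA_integer_ else 1L
          } else if (cls == "stop_lost") {
            if (l$n_codons %in% used_codons[[gid]]) NA_integer_ else l$n_codons
          } else {
            span <- FX_SLOT_SPAN[[cls]]
            take_slot(gid, span[1L], span[2L])
          }
          if (!is.na(slot)) {
            if (cls %in% c("start_lost", "stop_lost")) {
              used_codons[[gid]] <- c(used_codons[[gid]], slot)
            }
            plants[[length(plants) + 1L]] <-
              list(class = cls, gene_id = gid, slot = slot)
            break
          }
        }
      }
    }
  }

  # -- fix required codons at the planted slots ------------------------------
  for (p in plants) {
    if (is.null(p$slot)) next
    gid <- p$gene_id
    if (p$class %in% names(FX_SNV_RECIPES)) {
      layouts[[gid]]$codons[p$slot] <- FX_SNV_RECIPES[[p$class]][["codon"]]
    } else {
      pins <- FX_INDEL_PINS[[p$class]]
      for (off in names(pins)) {
        layouts[[gid]]$codons[p$slot + as.integer(off)] <- pins[[off]]
      }
    }
  }

  # -- embed gene sequences into the chromosomes -----------------------------
  for (gid in names(layouts)) {
    l <- layouts[[gid]]
    coding <- paste(l$codons, collapse = "")
    genomic <- if (l$strand == "+") coding else revcomp(coding)
    gchars <- strsplit(genomic, "")[[1L]]
    at <- 1L
    for (e in seq_len(l$n_exons)) {
      len <- l$exon_end[e] - l$exon_start[e] + 1L
      genome_chars[[l$chrom]][l$exon_start[e]:l$exon_end[e]] <-
        gchars[at:(at + len - 1L)]
      at <- at + len
    }
  }
  genome <- structure(vapply(genome_chars, paste, "", collapse = ""),
                      class = "genome_sequence")

  # -- realize planted variants as genomic REF/ALT ---------------------------
  truth <- do.call(rbind, lapply(plants, function(p) {
    v <- fx_realize_variant(p, layouts[[p$gene_id]], genome)
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               gene_id = v$gene_id, class = v$class,
               effect_term = v$effect_term, aa_notation = v$aa_notation,
               severity = v$severity, stringsAsFactors = FALSE)
  }))
  truth <- truth[order(match(truth$chrom, chroms), truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  for (ch in chroms) {
    d <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(d) > 1L &&
        any(d$pos[-1L] <= d$pos[-nrow(d)] + nchar(d$ref[-nrow(d)]) - 1L)) {
      stop("fixture internal error: overlapping planted variants")
    }
  }

  # -- genotypes (inbred panel: homozygous calls) ----------------------------
  accessions <- sprintf("ACC%04d", seq_len(spec$n_accessions))
  n_acc <- spec$n_accessions
  carrier_sets <- vector("list", nrow(truth))
  gt_mat <- matrix("0/0", nrow = nrow(truth), ncol = n_acc)
  for (i in seq_len(nrow(truth))) {
    n_car <- 1L + stats::rbinom(1L, max(n_acc - 2L, 0L), 0.25)
    carriers <- sort(sample(n_acc, n_car))
    carrier_sets[[i]] <- accessions[carriers]
    gt_mat[i, carriers] <- "1/1"
  }

  # -- mask genotype calls (majority-recoverable cells only) -----------------
  target <- round(spec$missing_rate * nrow(truth) * n_acc)
  masked <- matrix(FALSE, nrow = nrow(truth), ncol = n_acc)
  if (target > 0L) {
    cells <- cbind(rep(seq_len(nrow(truth)), n_acc),
                   rep(seq_len(n_acc), each = nrow(truth)))
    cells <- cells[sample(nrow(cells)), , drop = FALSE]
    n_masked <- 0L
    for (k in seq_len(nrow(cells))) {
      if (n_masked >= target) break
      i <- cells[k, 1L]; a <- cells[k, 2L]
      masked[i, a] <- TRUE
      fill <- fx_fill(gt_mat[i, !masked[i, ]])
      if (all(gt_mat[i, masked[i, ]] == fill)) {
        n_masked <- n_masked + 1L
      } else {
        masked[i, a] <- FALSE
      }
    }
  }
  hit <- which(masked, arr.ind = TRUE)
  masked_df <- data.frame(accession = accessions[hit[, 2L]],
                          chrom = truth$chrom[hit[, 1L]],
                          pos = truth$pos[hit[, 1L]],
                          stringsAsFactors = FALSE)
  masked_df <- masked_df[order(masked_df$accession, masked_df$chrom,
                               masked_df$pos), , drop = FALSE]
  rownames(masked_df) <- NULL

  # -- metadata --------------------------------------------------------------
  shuffled <- sample(accessions)
  n_per <- round(spec$category_proportions * n_acc)
  cat_of <- stats::setNames(rep(NA_character_, n_acc), accessions)
  at <- 0L
  for (ci in seq_along(spec$category_values)) {
    take <- shuffled[at + seq_len(min(n_per[ci], max(n_acc - at, 0L)))]
    cat_of[take] <- spec$category_values[ci]
    at <- at + length(take)
  }
  countries <- c("China", "USA", "Japan", "South Korea", "Russia")
  states <- c("", "MO", "IL", "Heilongjiang", "Jilin", "Hokkaido")
  meta_rows <- list()
  elite_seen <- 0L
  last_cat <- spec$category_values[length(spec$category_values)]
  for (a in accessions) {
    if (is.na(cat_of[[a]])) next
    cultivar <- ""
    if (identical(cat_of[[a]], last_cat)) {
      elite_seen <- elite_seen + 1L
      if (elite_seen %% 2L == 1L) cultivar <- "Yes"
    }
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      Accession = a, `Improvement Status` = cat_of[[a]], Cultivar = cultivar,
      `Maturity Group` = as.character(sample(0:7, 1L)),
      Country = sample(countries, 1L), State = sample(states, 1L),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  metadata <- if (length(meta_rows) > 0L) do.call(rbind, meta_rows) else {
    data.frame(Accession = character(0), `Improvement Status` = character(0),
               Cultivar = character(0), `Maturity Group` = character(0),
               Country = character(0), State = character(0),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  cspec <- category_spec("Improvement Status", spec$category_values,
                         flag_columns = "Cultivar")

  # -- variant records + gene models -----------------------------------------
  records <- lapply(seq_len(nrow(truth)), function(i) {
    gt <- t(vapply(seq_len(n_acc), function(a) {
      as.integer(strsplit(gt_mat[i, a], "/", fixed = TRUE)[[1L]])
    }, integer(2)))
    list(chrom = truth$chrom[i], pos = truth$pos[i], ref = truth$ref[i],
         alt = truth$alt[i], info = ".", gt = gt, missing = masked[i, ])
  })

  gene_models <- lapply(layouts, function(l) {
    segs <- data.frame(start = l$exon_start, end = l$exon_end)
    tx_order <- if (l$strand == "+") seq_len(l$n_exons) else rev(seq_len(l$n_exons))
    lens <- segs$end - segs$start + 1L
    phases <- integer(l$n_exons)
    cum <- 0L
    for (e in tx_order) {
      phases[e] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + lens[e]
    }
    gene_model(l$gene_id, l$chrom, l$gstart, l$gend, l$strand,
               list(list(transcript_id = l$transcript_id,
                         exons = segs, cds = cbind(segs, phase = phases))))
  })

  # -- ground-truth per-gene partitions, tables, summary ---------------------
  truth_genes <- fx_truth_genes(truth, carrier_sets, masked, accessions,
                                metadata, cspec, names(layouts))
  n_pos <- vapply(truth_genes, function(tg) length(tg$positions), 0L)
  n_all <- vapply(truth_genes, function(tg) length(tg$alleles), 0L)
  has_null <- vapply(names(layouts), function(gid) {
    any(truth$gene_id == gid & truth$severity == "null")
  }, TRUE)
  with_pos <- n_pos > 0L
  truth_summary <- list(
    n_genes = length(layouts),
    n_genes_reference_only = sum(!with_pos),
    n_genes_with_null_alleles = sum(has_null),
    n_modifying_variants = sum(truth$severity != "non_modifying"),
    n_null_variants = sum(truth$severity == "null"),
    mean_positions_per_gene = if (any(with_pos)) mean(n_pos[with_pos]) else NA_real_,
    median_positions_per_gene = if (any(with_pos)) stats::median(n_pos[with_pos]) else NA_real_,
    mean_alleles_per_gene = if (any(with_pos)) mean(n_all[with_pos]) else NA_real_,
    median_alleles_per_gene = if (any(with_pos)) stats::median(n_all[with_pos]) else NA_real_,
    mean_missing_per_accession = sum(masked) / n_acc)

  manifest <- list(
    spec = unclass(spec),
    accessions = accessions,
    variants = truth,
    carriers = stats::setNames(carrier_sets,
                               paste(truth$chrom, truth$pos, sep = ":")),
    masked = masked_df,
    genes = truth_genes,
    summary = truth_summary)

  # -- write files -----------------------------------------------------------
  files <- c(
    fasta = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "variants.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    category_spec = file.path(dir, "category_spec.json"),
    manifest = file.path(dir, "manifest.json"))
  write_genome_fasta(genome, files[["fasta"]])
  write_gene_models(gene_models, files[["gff"]])
  write_vcf_panel(accessions, records, files[["vcf"]], genome = genome)
  write_panel_metadata(metadata, files[["metadata"]])
  write_category_spec(cspec, files[["category_spec"]])
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(dir = dir, files = files, manifest = manifest)
}

# Turn a planted-variant plan entry into genomic REF/ALT plus expected effect,
# verifying that VCF-level normalization recovers the intended change.
fx_realize_variant <- function(p, l, genome) {
  cls <- p$class
  chrom_seq <- unclass(genome)[[l$chrom]]
  aas <- codon_aas(l$codons)
  mk <- function(pos, ref, alt, aa) {
    eff <- FX_CLASS_EFFECT[[cls]]
    list(chrom = l$chrom, pos = pos, ref = ref, alt = alt,
         gene_id = l$gene_id, class = cls, effect_term = eff,
         aa_notation = aa, severity = classify_severity(eff)$severity)
  }

  if (cls %in% c("splice_donor", "splice_acceptor", "intronic")) {
    ii <- p$intron
    is_ <- l$exon_end[ii] + 1L
    ie_ <- l$exon_start[ii + 1L] - 1L
    donor_first <- if (l$strand == "+") is_ else ie_
    acceptor_last <- if (l$strand == "+") ie_ else is_
    gpos <- switch(cls, splice_donor = donor_first,
                   splice_acceptor = acceptor_last,
                   intronic = (is_ + ie_) %/% 2L)
    ref <- substr(chrom_seq, gpos, gpos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    return(mk(gpos, ref, alt, ""))
  }

  slot <- p$slot
  tx_of <- function(codon_idx, off) 3L * (codon_idx - 1L) + off

  if (cls %in% names(FX_SNV_RECIPES)) {
    r <- FX_SNV_RECIPES[[cls]]
    off <- as.integer(r[["off"]])
    ti <- tx_of(slot, off)
    g <- l$tx2g[ti]
    ref <- substr(chrom_seq, g, g)
    alt <- if (l$strand == "+") r[["alt"]] else comp_base(r[["alt"]])
    alt_codon <- r[["codon"]]
    substr(alt_codon, off, off) <- r[["alt"]]
    return(mk(g, ref, alt, fx_snv_notation(cls, aas, slot, alt_codon)))
  }

  # transcript-level indel description: REF span [s, e], deletions keep the
  # transcript-level anchor base, insertions append after the anchor
  if (cls == "frameshift_deletion") {
    s <- tx_of(slot, 1L) - 1L; e <- tx_of(slot, 1L); ins <- ""
    aa <- paste0(aas[slot], slot, "fs")
  } else if (cls == "frameshift_insertion") {
    s <- tx_of(slot, 1L); e <- s; ins <- "G"
    aa <- paste0(aas[slot], slot, "fs")
  } else if (cls == "conservative_inframe_deletion") {
    s <- tx_of(slot, 1L) - 1L; e <- tx_of(slot, 3L); ins <- ""
    aa <- paste0(aas[slot], slot, "del")
  } else if (cls == "disruptive_inframe_deletion") {
    s <- tx_of(slot, 1L); e <- tx_of(slot + 1L, 1L); ins <- ""
    aa <- paste0(aas[slot], slot, "del")
  } else if (cls == "conservative_inframe_insertion") {
    s <- tx_of(slot, 3L); e <- s; ins <- "GCA"
    aa <- paste0(aas[slot + 1L], slot + 1L, "ins")
  } else if (cls == "disruptive_inframe_insertion") {
    s <- tx_of(slot, 1L); e <- s; ins <- "GCA"
    aa <- paste0(aas[slot], slot, "ins")
  } else {
    stop("fixture internal error: unhandled class ", cls)
  }

  span <- l$tx2g[s:e]
  if (length(span) > 1L && !all(abs(diff(span)) == 1L)) {
    stop("fixture internal error: planted indel spans an intron")
  }
  g1 <- min(span); g2 <- max(span)
  coding <- paste(l$codons, collapse = "")
  ref_t <- substr(coding, s, e)
  is_insertion <- nzchar(ins)
  alt_t <- if (is_insertion) paste0(ref_t, ins) else substr(ref_t, 1L, 1L)
  if (l$strand == "+") {
    ref_g <- ref_t; alt_g <- alt_t
  } else {
    ref_g <- revcomp(ref_t); alt_g <- revcomp(alt_t)
  }
  pos <- g1
  stopifnot(identical(substr(chrom_seq, g1, g2), ref_g))

  # the VCF-level trim must recover the intended transcript-level change
  core <- trim_ref_alt(pos, ref_g, alt_g)
  if (is_insertion) {
    anchor_g <- if (l$strand == "-") core$g_start else core$g_start - 1L
    ok <- nchar(core$ref_core) == 0L &&
      identical(match(anchor_g, l$tx2g), s) &&
      identical(if (l$strand == "+") core$alt_core else revcomp(core$alt_core),
                ins)
  } else {
    want <- range(l$tx2g[(s + 1L):e])
    ok <- nchar(core$alt_core) == 0L &&
      core$g_start == want[1L] && core$g_end == want[2L]
  }
  if (!ok) {
    stop("fixture internal error: ambiguous planted indel at ", l$gene_id,
         " codon ", slot, " (", cls, ")")
  }
  mk(pos, ref_g, alt_g, aa)
}

# Expected amino-acid notation for the SNV recipes.
fx_snv_notation <- function(cls, aas, slot, alt_codon) {
  switch(cls,
         missense = paste0(aas[slot], slot, codon_aas(alt_codon)),
         synonymous = "",
         stop_gained = paste0(aas[slot], slot, "*"),
         stop_lost = paste0("*", slot, "ext"),
         start_lost = "M1?")
}

# Constructive per-gene truth: catalog positions, allele partition in the
# contract order (Total descending, state-vector lexicographic ties),
# frequency tables, per-accession gene imputation flags.
fx_truth_genes <- function(truth, carrier_sets, masked, accessions,
                           metadata, cspec, gene_ids) {
  n_acc <- length(accessions)
  carrier_keys <- paste(truth$chrom, truth$pos, sep = ":")
  out <- list()
  for (gid in gene_ids) {
    rows <- which(truth$gene_id == gid & truth$severity != "non_modifying")
    rows <- rows[order(truth$pos[rows])]
    labels <- if (length(rows) == 0L) character(0) else {
      position_label(truth$chrom[rows], truth$pos[rows])
    }
    states <- matrix("", nrow = n_acc, ncol = length(rows))
    imput <- matrix(FALSE, nrow = n_acc, ncol = length(rows))
    for (j in seq_along(rows)) {
      i <- rows[j]
      carrier <- accessions %in% carrier_sets[[i]]
      states[, j] <- ifelse(carrier, truth$alt[i], truth$ref[i])
      imput[, j] <- masked[i, ]
    }
    keys <- if (length(rows) == 0L) rep("", n_acc) else {
      apply(states, 1L, paste, collapse = "\x1f")
    }
    groups <- split(seq_len(n_acc), keys)
    groups <- groups[order(-lengths(groups), names(groups))]
    alleles <- lapply(seq_along(groups), function(k) {
      members <- groups[[k]]
      list(index = k,
           states = if (length(rows) == 0L) character(0) else states[members[1L], ],
           carriers = accessions[members],
           total = length(members))
    })
    freq <- lapply(alleles, function(al) {
      cats <- vapply(al$carriers, function(a) {
        accession_category(metadata, cspec, a)
      }, "", USE.NAMES = FALSE)
      counts <- vapply(cspec$category_values, function(v) {
        sum(!is.na(cats) & cats == v)
      }, 0L)
      flags <- vapply(cspec$flag_columns, function(fc) {
        sum(vapply(al$carriers, function(a) {
          accession_flag(metadata, cspec, a, fc)
        }, TRUE))
      }, 0L)
      c(list(Allele = al$index), as.list(counts), as.list(flags),
        list(Total = al$total))
    })
    gene_flag <- vapply(seq_len(n_acc), function(a) {
      if (length(rows) > 0L && any(imput[a, ])) "+" else "-"
    }, "")
    out[[gid]] <- list(positions = labels, alleles = alleles,
                       frequency = freq,
                       gene_imputation = stats::setNames(gene_flag, accessions))
  }
  out
}

#' Check pipeline outputs against a fixture's ground truth
#'
#' Compares effect calls, per-gene allele partitions (membership, totals and
#' order), frequency tables, imputation flags (per cell and per gene) and the
#' dataset summary against the manifest. An empty report is a pass.
#'
#' @param catalog An `allele_catalog` built from the fixture's files.
#' @param manifest The manifest from [generate_fixture()].
#' @return A data.frame with columns `component`, `where`, `detail`; zero rows
#'   when every check passes.
#' @export
verify_against_truth <- function(catalog, manifest) {
  report <- list()
  flag <- function(component, where, detail) {
    report[[length(report) + 1L]] <<- data.frame(
      component = component, where = where, detail = detail,
      stringsAsFactors = FALSE)
  }
  truth <- as.data.frame(manifest$variants, stringsAsFactors = FALSE)
  eff <- catalog$effects

  # effect calls
  for (i in seq_len(nrow(truth))) {
    where <- paste0(truth$chrom[i], ":", truth$pos[i], ">", truth$alt[i],
                    " (", truth$gene_id[i], ")")
    j <- which(eff$chrom == truth$chrom[i] & eff$pos == truth$pos[i] &
                 eff$alt == truth$alt[i] & eff$gene_id == truth$gene_id[i])
    if (length(j) != 1L) {
      flag("effects", where, "no unique annotation row")
      next
    }
    for (fld in c("effect_term", "aa_notation", "severity")) {
      if (eff[[fld]][j] != truth[[fld]][i]) {
        flag("effects", where,
             paste0(fld, " ", eff[[fld]][j], " != ", truth[[fld]][i]))
      }
    }
  }

  # per-gene partitions, tables, gene-level imputation flags
  for (gid in names(manifest$genes)) {
    tg <- manifest$genes[[gid]]
    alleles <- catalog$alleles[[gid]]
    pos_df <- attr(alleles, "positions")
    t_pos <- as.character(unlist(tg$positions) %||% character(0))
    if (!identical(as.character(pos_df$label), t_pos)) {
      flag("positions", gid,
           paste0("[", paste(pos_df$label, collapse = ","), "] != [",
                  paste(t_pos, collapse = ","), "]"))
      next
    }
    if (length(alleles) != length(tg$alleles)) {
      flag("partition", gid, paste0("allele count ", length(alleles),
                                    " != ", length(tg$alleles)))
      next
    }
    for (k in seq_along(tg$alleles)) {
      ta <- tg$alleles[[k]]
      al <- alleles[[k]]
      if (!identical(as.character(al$states),
                     as.character(unlist(ta$states) %||% character(0)))) {
        flag("partition", paste0(gid, " allele ", k), "state vector mismatch")
        next
      }
      if (al$total != ta$total || !setequal(al$carriers, unlist(ta$carriers))) {
        flag("partition", paste0(gid, " allele ", k), "carriers mismatch")
      }
    }
    freq <- catalog$frequencies[[gid]]
    for (k in seq_along(tg$frequency)) {
      tf <- tg$frequency[[k]]
      for (col in names(tf)) {
        if (!isTRUE(all.equal(as.numeric(freq[k, col]),
                              as.numeric(tf[[col]])))) {
          flag("frequency", paste0(gid, " allele ", k, " ", col),
               paste0(freq[k, col], " != ", tf[[col]]))
        }
      }
    }
    t_flag <- unlist(tg$gene_imputation)
    for (al in alleles) {
      for (m in seq_along(al$carriers)) {
        if (!al$carriers[m] %in% names(t_flag)) {
          flag("partition", gid,
               paste0("carrier ", al$carriers[m], " not in panel"))
          next
        }
        got <- gene_imputation_flag(al$imputed[m, ])
        if (got != t_flag[[al$carriers[m]]]) {
          flag("imputation", paste0(gid, " ", al$carriers[m]),
               paste0("gene flag ", got, " != ", t_flag[[al$carriers[m]]]))
        }
      }
    }
  }

  # per-cell imputation flags against the masked-cell list
  masked <- as.data.frame(manifest$masked, stringsAsFactors = FALSE)
  mkeys <- if (nrow(masked) > 0L) {
    paste(masked$accession, masked$chrom, masked$pos, sep = "\r")
  } else character(0)
  got_keys <- character(0)
  for (rec in catalog$records) {
    h <- which(rec$missing)
    if (length(h) > 0L) {
      got_keys <- c(got_keys, paste(catalog$accessions[h], rec$chrom,
                                    rec$pos, sep = "\r"))
    }
  }
  if (!setequal(got_keys, mkeys)) {
    flag("imputation", "panel",
         paste0("imputed-cell set mismatch (", length(got_keys), " vs ",
                length(mkeys), ")"))
  }

  # summary
  for (fld in names(manifest$summary)) {
    want <- manifest$summary[[fld]]
    got <- catalog$summary[[fld]]
    same <- if (is.null(want) || is.na(want)) is.na(got) else {
      isTRUE(all.equal(as.numeric(got), as.numeric(want)))
    }
    if (!same) flag("summary", fld, paste0(got, " != ", want))
  }

  if (length(report) == 0L) {
    return(data.frame(component = character(0), where = character(0),
                      detail = character(0)))
  }
  do.call(rbind, report)
}
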