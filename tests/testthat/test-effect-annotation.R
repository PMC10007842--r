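test_that("primary transcript is longest CDS with lexicographic tie-break", {
  mk_tx <- function(id, start, end) {
    list(transcript_id = id,
         exons = data.frame(start = start, end = end),
         cds = data.frame(start = start, end = end, phase = 0L))
  }
  g <- gene_model("g", "chr1", 1L, 1000L, "+",
                  list(mk_tx("t1", 1L, 300L), mk_tx("t2", 1L, 450L)))
  expect_equal(primary_transcript(g), "t2")
  g2 <- gene_model("g", "chr1", 1L, 1000L, "+",
                   list(mk_tx("t2", 1L, 300L), mk_tx("t1", 101L, 400L)))
  expect_equal(primary_transcript(g2), "t1")
  g3 <- gene_model("g", "chr1", 1L, 1000L, "+", list(
    list(transcript_id = "t1",
         exons = data.frame(start = 1L, end = 300L),
         cds = data.frame(start = integer(0), end = integer(0),
                          phase = integer(0)))))
  expect_error(primary_transcript(g3), "no coding transcript")
})

test_that("CDS extraction is strand-aware and translation stops at stops", {
  genome <- toy_genome()
  expect_equal(extract_cds(genome, toy_gene("+")), "ATGACTGGGTTGTAA")
  # minus strand: independent reverse-complement oracle
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGACTGGGTTGTAA")))
  expect_equal(extract_cds(genome, toy_gene("-")), rc)
  expect_equal(rc, "TTACAACCCAGTCAT")

  # two-segment CDS concatenates in transcript order
  expect_equal(extract_cds(toy_split_genome(), toy_split_gene()),
               "ATGACTGGGTTGTAA")

  expect_equal(translate_cds("ATGACTGGGTTGTAA"), "MTGL*")
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("ATGNNN"), "MX")
  expect_equal(translate_cds("ATGACTGGGT"), "MTG")  # trailing partial codon
  expect_error(translate_cds("AT"), "shorter")
})

test_that("SNVs classify by codon comparison with compact notation", {
  genome <- toy_genome()
  gene <- toy_gene("+")
  # codon 2 ACT -> GCT: Thr -> Ala
  v <- make_record("chr1", 14, "A", "G", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "missense_variant")
  expect_equal(e$aa_notation, "T2A")
  expect_equal(e$severity, "modifying")
  expect_equal(e$display_color, "blue")
  # codon 4 TTG -> TAG: premature stop
  v <- make_record("chr1", 21, "T", "A", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "stop_gained")
  expect_equal(e$aa_notation, "L4*")
  # synonymous: codon 3 GGG -> GGA
  v <- make_record("chr1", 19, "G", "A", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "synonymous_variant")
  expect_equal(e$aa_notation, "")
  expect_equal(e$severity, "non_modifying")
  # start codon ATG -> ACG
  v <- make_record("chr1", 12, "T", "C", list(c(1, 1)))
  expect_equal(annotate_variant(v, 1L, gene, genome)$effect_term, "start_lost")
  # stop codon TAA -> TAC
  v <- make_record("chr1", 25, "A", "C", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "stop_lost")
  expect_equal(e$aa_notation, "*5ext")
  # outside the gene's CDS
  v <- make_record("chr1", 3, "C", "A", list(c(1, 1)))
  expect_equal(annotate_variant(v, 1L, gene, genome)$effect_term,
               "non_coding_or_other")
  expect_error(annotate_variant(v, 2L, gene, genome), "out of range")
})

test_that("indels classify by net length and codon alignment", {
  genome <- toy_genome()
  gene <- toy_gene("+")
  # deletion of codon-2 second base: frameshift at Thr2
  v <- make_record("chr1", 14, "AC", "A", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "frameshift_variant")
  expect_equal(e$aa_notation, "T2fs")
  expect_equal(e$severity, "null")
  # deletion of exactly codon 2 (codon-aligned): conservative, T2del
  v <- make_record("chr1", 13, "GACT", "G", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "conservative_inframe_deletion")
  expect_equal(e$aa_notation, "T2del")
  # three-base deletion spanning codons 2 and 3: disruptive
  v <- make_record("chr1", 14, "ACTG", "A", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "disruptive_inframe_deletion")
  # insertion of one codon at the codon 2/3 boundary: conservative
  v <- make_record("chr1", 16, "T", "TGCA", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "conservative_inframe_insertion")
  expect_equal(e$aa_notation, "G3ins")
  # one-base insertion inside codon 2: frameshift
  v <- make_record("chr1", 14, "A", "AG", list(c(1, 1)))
  e <- annotate_variant(v, 1L, gene, genome)
  expect_equal(e$effect_term, "frameshift_variant")
})

test_that("a 6-base in-frame deletion is never called a frameshift", {
  # CDS containing the literal heptamer CTTGTTA anchored mid-codon
  codons <- c("ATG", "CTT", "GTT", "AGG", "ACT", "GGA", "TGT", "TAA")
  built <- gene_from_codons(codons)
  pos <- built$start + 3L  # transcript position 4, the C of codon 2
  ref <- "CTTGTTA"
  alt <- "C"
  expect_equal(substr(unclass(built$genome)[[1L]], pos, pos + 6L), ref)
  v <- make_record("chr1", pos, ref, alt, list(c(1, 1)))
  e <- annotate_variant(v, 1L, built$gene, built$genome)
  expect_equal(e$effect_term, "disruptive_inframe_deletion")
  expect_false(e$effect_term == "frameshift_variant")
  expect_equal(classify_severity(e$effect_term)$severity, "modifying")
})

test_that("notation matches the field's compact style at larger residues", {
  # Thr at codon 27 mutated A->G at its first base: T27A
  codons <- c("ATG", rep("GGA", 25), "ACT", rep("CCT", 50), "CGT",
              rep("GGC", 5), "TAA")
  built <- gene_from_codons(codons)
  g <- built$start + 3L * 26L  # first base of codon 27
  v <- make_record("chr1", g, "A", "G", list(c(1, 1)))
  e <- annotate_variant(v, 1L, built$gene, built$genome)
  expect_equal(e$effect_term, "missense_variant")
  expect_equal(e$aa_notation, "T27A")

  # frameshift first affecting Arg 75: R75fs
  expect_equal(codon_aas(codons[78]), "R")
  anchor <- built$start + 3L * 77L - 1L  # last base of codon 77
  ref <- substr(unclass(built$genome)[[1L]], anchor, anchor + 1L)
  v <- make_record("chr1", anchor, ref, substr(ref, 1L, 1L), list(c(1, 1)))
  e <- annotate_variant(v, 1L, built$gene, built$genome)
  expect_equal(e$effect_term, "frameshift_variant")
  expect_equal(e$aa_notation, "R78fs")
})

test_that("splice-core variants take precedence and use the intron ends", {
  genome <- toy_split_genome()
  gene <- toy_split_gene()
  # intron is 19..38 on the plus strand: donor 19-20, acceptor 37-38
  for (pos in c(19L, 20L)) {
    v <- make_record("chr1", pos, substr(unclass(genome)[[1L]], pos, pos),
                     "A", list(c(1, 1)))
    if (v$ref == v$alt) v$alt <- "C"
    expect_equal(annotate_variant(v, 1L, gene, genome)$effect_term,
                 "splice_donor_variant")
  }
  for (pos in c(37L, 38L)) {
    v <- make_record("chr1", pos, substr(unclass(genome)[[1L]], pos, pos),
                     "T", list(c(1, 1)))
    if (v$ref == v$alt) v$alt <- "C"
    e <- annotate_variant(v, 1L, gene, genome)
    expect_equal(e$effect_term, "splice_acceptor_variant")
    expect_equal(e$severity, "null")
    expect_equal(e$display_color, "green")
  }
  # mid-intron SNV is non-coding
  v <- make_record("chr1", 28, substr(unclass(genome)[[1L]], 28, 28), "A",
                   list(c(1, 1)))
  if (v$ref == v$alt) v$alt <- "C"
  expect_equal(annotate_variant(v, 1L, gene, genome)$effect_term,
               "non_coding_or_other")
})

test_that("severity classes and display colors cover the whole vocabulary", {
  expect_equal(classify_severity("missense_variant"),
               list(severity = "modifying", display_color = "blue"))
  expect_equal(classify_severity("splice_donor_variant"),
               list(severity = "null", display_color = "green"))
  expect_equal(classify_severity("synonymous_variant"),
               list(severity = "non_modifying", display_color = "white"))
  expect_equal(classify_severity("conservative_inframe_deletion"),
               list(severity = "modifying", display_color = "orange"))
  expect_equal(classify_severity("disruptive_inframe_insertion"),
               list(severity = "modifying", display_color = "white"))
  for (term in c("stop_gained", "stop_lost", "start_lost",
                 "frameshift_variant")) {
    expect_equal(classify_severity(term),
                 list(severity = "null", display_color = "red"))
  }
  # total and deterministic over the vocabulary
  for (term in allelecat:::EFFECT_TERMS) {
    a <- classify_severity(term)
    expect_true(a$severity %in% c("null", "modifying", "non_modifying"))
    expect_identical(a, classify_severity(term))
  }
  expect_error(classify_severity("upstream_gene_variant"), "unknown")
})

test_that("mirrored genes on opposite strands give identical calls", {
  codons <- c("ATG", "ACT", "GGG", "TTG", "CGT", "GGC", "TAC", "TAA")
  plus <- gene_from_codons(codons, offset = 20L, strand = "+")
  chrom_plus <- unclass(plus$genome)[[1L]]
  L <- nchar(chrom_plus)
  chrom_minus <- oracle_revcomp(chrom_plus)
  genome_minus <- structure(c(chr1 = chrom_minus), class = "genome_sequence")
  start_m <- L - plus$end + 1L
  end_m <- L - plus$start + 1L
  gene_minus <- gene_model("g1", "chr1", start_m, end_m, "-", list(
    list(transcript_id = "g1.t1",
         exons = data.frame(start = start_m, end = end_m),
         cds = data.frame(start = start_m, end = end_m, phase = 0L))))

  mirror <- function(pos, ref, alt) {
    list(pos = L - (pos + nchar(ref) - 1L) + 1L,
         ref = oracle_revcomp(ref), alt = oracle_revcomp(alt))
  }
  cases <- list(
    list(pos = plus$start + 3L, ref = "A", alt = "G"),          # missense
    list(pos = plus$start + 2L, ref = "GA", alt = "G"),         # frameshift
    list(pos = plus$start + 5L, ref = "TGGG", alt = "T"),       # inframe del
    list(pos = plus$start + 11L, ref = "G", alt = "GGCA"))      # inframe ins
  for (cs in cases) {
    e_plus <- annotate_variant(
      make_record("chr1", cs$pos, cs$ref, cs$alt, list(c(1, 1))),
      1L, plus$gene, plus$genome)
    m <- mirror(cs$pos, cs$ref, cs$alt)
    e_minus <- annotate_variant(
      make_record("chr1", m$pos, m$ref, m$alt, list(c(1, 1))),
      1L, gene_minus, genome_minus)
    expect_equal(e_minus$effect_term, e_plus$effect_term)
    expect_equal(e_minus$aa_notation, e_plus$aa_notation)
  }
})

test_that("ANN-style annotation strings map onto the internal vocabulary", {
  info <- paste0(
    "DP=10;ANN=G|missense_variant|MODERATE|GENE001|GENE001|transcript|",
    "GENE001.1|protein_coding|1/1|c.79A>G|p.Thr27Ala|79|79|27||,",
    "T|inframe_deletion|MODERATE|GENE002|GENE002|transcript|GENE002.1|",
    "protein_coding|1/1|c.1del|p.Thr2del|1|1|2||")
  ann <- parse_ann_entries(info)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$effect_term[1L], "missense_variant")
  expect_equal(ann$aa_notation[1L], "T27A")
  expect_equal(ann$effect_term[2L], "conservative_inframe_deletion")
  expect_equal(ann$gene_id[1L], "GENE001")
  expect_equal(nrow(parse_ann_entries("DP=10")), 0L)
})
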