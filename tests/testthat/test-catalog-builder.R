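toy_effects <- function() {
  data.frame(
    chrom = "chr1", pos = c(14L, 19L, 28L), ref = "A",
    alt = "G", alt_index = 1L, gene_id = "toy2", transcript_id = "toy2.t1",
    effect_term = c("missense_variant", "synonymous_variant",
                    "splice_donor_variant"),
    aa_notation = c("T2A", "", ""),
    severity = c("modifying", "non_modifying", "null"),
    display_color = c("blue", "white", "green"),
    stringsAsFactors = FALSE)
}

test_that("only modifying and null effects enter a gene's variant set", {
  genes <- list(toy2 = toy_split_gene())
  sets <- assign_variants_to_genes(toy_effects(), genes)
  expect_named(sets, "toy2")
  expect_equal(sets$toy2$pos, c(14L, 28L))  # synonymous excluded, sorted
  expect_equal(sets$toy2$effect_term,
               c("missense_variant", "splice_donor_variant"))
})

test_that("alleles group accessions by state vector with Total-descending order", {
  gene_set <- data.frame(
    chrom = "chr1", pos = c(14L, 28L), ref = c("A", "C"), alt = c("G", "T"),
    alt_index = 1L, effect_term = c("missense_variant", "stop_gained"),
    aa_notation = c("T2A", "W9*"), severity = c("modifying", "null"),
    display_color = c("blue", "red"), stringsAsFactors = FALSE)
  records <- list(
    make_record("chr1", 14, "A", "G", list(c(0, 0), c(1, 1), c(0, 0))),
    make_record("chr1", 28, "C", "T", list(c(0, 0), c(0, 0), c(0, 0))))
  alleles <- assemble_alleles(gene_set, records, c("a", "b", "c"))
  expect_length(alleles, 2L)
  expect_equal(alleles[[1L]]$total, 2L)
  expect_equal(alleles[[1L]]$states, c("A", "C"))   # reference allele first
  expect_equal(alleles[[1L]]$carriers, c("a", "c"))
  expect_equal(alleles[[2L]]$total, 1L)
  expect_equal(alleles[[2L]]$states, c("G", "C"))
  expect_equal(alleles[[2L]]$effect_term, c("missense_variant", ""))
  expect_equal(alleles[[2L]]$aa_notation, c("T2A", ""))
  # partition conservation
  expect_equal(sum(vapply(alleles, `[[`, 0L, "total")), 3L)
})

test_that("a gene with no modifying positions has one all-reference allele", {
  empty_set <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), alt_index = integer(0), effect_term = character(0),
    aa_notation = character(0), severity = character(0),
    display_color = character(0), stringsAsFactors = FALSE)
  alleles <- assemble_alleles(empty_set, list(), letters[1:5])
  expect_length(alleles, 1L)
  expect_equal(alleles[[1L]]$total, 5L)
  expect_equal(alleles[[1L]]$states, character(0))
  expect_equal(alleles[[1L]]$carriers, letters[1:5])
})

test_that("heterozygous and multi-allelic states render deterministically", {
  gene_set <- data.frame(
    chrom = "chr1", pos = 14L, ref = "A", alt = c("G", "T"),
    alt_index = c(1L, 2L),
    effect_term = c("missense_variant", "stop_gained"),
    aa_notation = c("T2A", "T2*"), severity = c("modifying", "null"),
    display_color = c("blue", "red"), stringsAsFactors = FALSE)
  records <- list(
    make_record("chr1", 14, "A", c("G", "T"),
                list(c(0, 1), c(2, 2), c(1, 2), c(0, 0))))
  alleles <- assemble_alleles(gene_set, records, c("a", "b", "c", "d"))
  states <- vapply(alleles, function(al) al$states, "")
  expect_setequal(states, c("A/G", "T", "G/T", "A"))
  het <- alleles[[which(states == "A/G")]]
  expect_equal(het$effect_term, "missense_variant")
  multi <- alleles[[which(states == "G/T")]]
  expect_equal(multi$effect_term, "missense_variant")  # lowest alt index
})

test_that("frequency tables count categories, flags and uncategorized totals", {
  meta <- data.frame(
    Accession = c("s1", "s2", "s3", "s4", "s5", "e1", "e2"),
    `Improvement Status` = c(rep("G. soja", 5L), "Elite", "Elite"),
    Cultivar = c(rep("", 5L), "Yes", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
  spec <- category_spec("Improvement Status",
                        c("G. soja", "Landrace", "Elite"),
                        flag_columns = "Cultivar")
  alleles <- list(
    list(index = 1L, states = "G",
         carriers = c("s1", "s2", "s3", "s4", "s5", "u1", "u2"), total = 7L),
    list(index = 2L, states = "A", carriers = c("e1", "e2"), total = 2L))
  tab <- build_frequency_table(alleles, meta, spec)
  expect_equal(names(tab),
               c("Allele", "G. soja", "Landrace", "Elite", "Cultivar", "Total"))
  expect_equal(tab[["G. soja"]], c(5L, 0L))
  expect_equal(tab$Landrace, c(0L, 0L))
  expect_equal(tab$Total, c(7L, 2L))      # uncategorized only in Total
  expect_equal(tab$Cultivar, c(0L, 1L))   # flag independent of partition
  expect_true(all(tab[["G. soja"]] + tab$Landrace + tab$Elite <= tab$Total))

  empty <- build_frequency_table(alleles, meta, empty_category_spec())
  expect_equal(names(empty), c("Allele", "Total"))

  bad <- category_spec("No Such Column", "x")
  expect_error(build_frequency_table(alleles, meta, bad), "not present")
})

test_that("allele partitions conserve accessions and categories on fixtures", {
  for (seed in c(21, 22, 23)) {
    built <- fixture_build(seed)
    catalog <- built$catalog
    n_acc <- length(catalog$accessions)
    spec <- catalog$category_spec
    cat_sizes <- vapply(spec$category_values, function(v) {
      sum(vapply(catalog$accessions, function(a) {
        identical(accession_category(catalog$metadata, spec, a), v)
      }, TRUE))
    }, 0L)
    for (gid in names(catalog$alleles)) {
      alleles <- catalog$alleles[[gid]]
      totals <- vapply(alleles, `[[`, 0L, "total")
      expect_equal(sum(totals), n_acc)
      expect_true(all(diff(totals) <= 0L))  # non-increasing order
      # each accession carried exactly once
      all_carriers <- unlist(lapply(alleles, `[[`, "carriers"))
      expect_setequal(all_carriers, catalog$accessions)
      expect_equal(anyDuplicated(all_carriers), 0L)
      # at most one all-reference allele
      n_ref_alleles <- sum(vapply(alleles, function(al) {
        length(al$states) > 0L && all(al$effect_term == "")
      }, TRUE))
      expect_lte(n_ref_alleles, 1L)
      # per-category counts sum to category sizes
      freq <- catalog$frequencies[[gid]]
      for (v in spec$category_values) {
        expect_equal(sum(freq[[v]]), unname(cat_sizes[[v]]))
      }
    }
  }
})

test_that("catalog summaries count genes, variants and missingness", {
  spec <- fixture_spec(seed = 24, missing_rate = 0)
  fx <- generate_fixture(spec, withr::local_tempdir())
  catalog <- build_catalog_from_files(
    fx$files[["fasta"]], fx$files[["gff"]], fx$files[["vcf"]],
    fx$files[["metadata"]], fx$files[["category_spec"]])
  s <- catalog$summary
  truth <- fx$manifest$variants
  expect_equal(s$n_genes, 6L)
  expect_equal(s$n_genes_reference_only,
               sum(!names(catalog$genes) %in%
                     truth$gene_id[truth$severity != "non_modifying"]))
  expect_gte(s$n_genes_reference_only, 1L)
  expect_equal(s$n_modifying_variants,
               sum(truth$severity != "non_modifying"))
  expect_equal(s$n_null_variants, sum(truth$severity == "null"))
  expect_lte(s$n_null_variants, s$n_modifying_variants)
  expect_equal(s$mean_missing_per_accession, 0)
  # denominators: genes with at least one modifying position
  n_pos <- vapply(catalog$gene_sets, function(d) {
    length(unique(d$pos))
  }, 0L)
  expect_equal(s$mean_positions_per_gene, mean(n_pos[n_pos > 0L]))
  expect_equal(s$median_alleles_per_gene,
               stats::median(lengths(catalog$alleles)[n_pos > 0L]))
})

test_that("repeat builds are byte-identical in row and table order", {
  fx <- fixture_build(21)
  catalog2 <- build_catalog_from_files(
    fx$fx$files[["fasta"]], fx$fx$files[["gff"]], fx$fx$files[["vcf"]],
    fx$fx$files[["metadata"]], fx$fx$files[["category_spec"]])
  for (gid in names(fx$catalog$alleles)) {
    expect_identical(catalog_rows(fx$catalog, gid),
                     catalog_rows(catalog2, gid))
    expect_identical(fx$catalog$frequencies[[gid]],
                     catalog2$frequencies[[gid]])
  }
})
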