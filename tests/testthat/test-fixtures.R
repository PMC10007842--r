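test_that("the same seed regenerates byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- generate_fixture(fixture_spec(seed = 7), d1)
  fx2 <- generate_fixture(fixture_spec(seed = 7), d2)
  for (f in names(fx1$files)) {
    expect_identical(unname(tools::md5sum(fx1$files[[f]])),
                     unname(tools::md5sum(fx2$files[[f]])),
                     label = paste("file", f))
  }
  # a different seed changes the panel
  fx3 <- generate_fixture(fixture_spec(seed = 8), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(fx1$files[["vcf"]])),
                         unname(tools::md5sum(fx3$files[["vcf"]]))))
})

test_that("the manifest reflects the planted plan by construction", {
  plan <- c(missense = 3L, frameshift_deletion = 2L, splice_donor = 1L,
            synonymous = 2L)
  spec <- fixture_spec(seed = 41, plan = plan)
  fx <- generate_fixture(spec, withr::local_tempdir())
  truth <- fx$manifest$variants
  expect_equal(nrow(truth), 8L)
  expect_equal(sum(truth$severity != "non_modifying"), 6L)
  expect_equal(sum(truth$severity == "non_modifying"), 2L)
  expect_equal(sum(truth$class == "missense"), 3L)
  expect_equal(unique(truth$effect_term[truth$class == "splice_donor"]),
               "splice_donor_variant")
  # gene 1 never receives a modifying variant
  g1 <- names(fx$manifest$genes)[1L]
  expect_false(g1 %in% truth$gene_id[truth$severity != "non_modifying"])
})

test_that("masked calls hit the requested rate at seed-determined cells", {
  spec <- fixture_spec(seed = 42, n_accessions = 10L,
                       plan = c(missense = 4L, stop_gained = 2L,
                                frameshift_deletion = 2L),
                       missing_rate = 0.05)
  fx <- generate_fixture(spec, withr::local_tempdir())
  expect_equal(nrow(fx$manifest$masked), round(0.05 * 10 * 8))
  # masked cells are majority-recoverable: the pipeline restores the planted
  # genotype, so truth verification stays exact
  catalog <- build_catalog_from_files(
    fx$files[["fasta"]], fx$files[["gff"]], fx$files[["vcf"]],
    fx$files[["metadata"]], fx$files[["category_spec"]])
  expect_equal(nrow(verify_against_truth(catalog, fx$manifest)), 0L)
})

test_that("infeasible plans are rejected with a spec error", {
  expect_error(
    generate_fixture(fixture_spec(seed = 1, n_genes = 1L,
                                  plan = c(splice_donor = 1L)),
                     withr::local_tempdir()),
    "fixture spec error")
  expect_error(fixture_spec(seed = 1, plan = c(nonsense_class = 1L)),
               "unknown variant class")
  expect_error(fixture_spec(seed = 1, category_proportions = c(0.9, 0.9)),
               "proportions")
})

test_that("fixture files parse cleanly with external grammar expectations", {
  fx <- fixture_build(43)$fx
  # VCF: header then 10 columns minimum, tab-delimited
  lines <- readLines(fx$files[["vcf"]])
  expect_true(startsWith(lines[1L], "##fileformat=VCFv4"))
  header <- grep("^#CHROM", lines)
  expect_length(header, 1L)
  body <- strsplit(lines[(header + 1L):length(lines)], "\t", fixed = TRUE)
  expect_true(all(lengths(body) == lengths(body)[1L]))
  expect_true(all(vapply(body, function(f) f[9L] == "GT", TRUE)))
  # GFF3: 9 columns everywhere
  glines <- readLines(fx$files[["gff"]])
  expect_equal(glines[1L], "##gff-version 3")
  gbody <- strsplit(glines[-1L], "\t", fixed = TRUE)
  expect_true(all(lengths(gbody) == 9L))
})

test_that("induced faults are caught by truth verification", {
  built <- fixture_build(43)
  catalog <- built$catalog
  manifest <- built$fx$manifest

  # severity table corrupted: a missense recorded as null inflates the
  # null-variant count
  broken <- catalog
  broken$summary$n_null_variants <- broken$summary$n_null_variants + 1L
  rep1 <- verify_against_truth(broken, manifest)
  expect_true("n_null_variants" %in% rep1$where[rep1$component == "summary"])

  # dropped imputation flags flip gene-level +/- columns
  if (nrow(manifest$masked) > 0L) {
    broken2 <- catalog
    broken2$records <- lapply(broken2$records, function(r) {
      r$missing <- rep(FALSE, length(r$missing))
      r
    })
    broken2$alleles <- lapply(broken2$alleles, function(als) {
      out <- lapply(als, function(al) {
        al$imputed[] <- FALSE
        al
      })
      attributes(out) <- attributes(als)
      out
    })
    rep2 <- verify_against_truth(broken2, manifest)
    expect_true(any(rep2$component == "imputation"))
  }

  # mislabelled carrier breaks the partition check
  broken3 <- catalog
  gid <- names(Filter(function(a) length(a) > 1L, broken3$alleles))[1L]
  broken3$alleles[[gid]][[1L]]$carriers[1L] <- "ACC9999"
  rep3 <- verify_against_truth(broken3, manifest)
  expect_true(any(rep3$component == "partition"))
})
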