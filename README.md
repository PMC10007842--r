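# allelecat

Gene-level allele catalogs from multi-sample variant panels.

Re-sequenced germplasm panels (soybean, maize, *Arabidopsis*, ...) hold
thousands of accessions and tens of millions of variant positions, but the
question a breeder or geneticist usually asks is gene-shaped: *which alleles
of my candidate gene exist in the panel, what do they do to the protein, and
who carries them?* `allelecat` answers it by collating, for every gene, the
variant positions whose predicted effect modifies the gene product, and
defining an **allele** as the unique combination of reference/alternate
genotype states over those positions — a gene-level haplotype class. Allele
carrier counts are tabulated by accession category (e.g. *G. soja* /
Landrace / Elite improvement status, with an independent Cultivar flag), so
rare loss-of-function alleles and their breeding history are visible at a
glance.

The package implements the full computation behind such a catalog:

* **IO** — FASTA, GFF3, VCF 4.x (via Biostrings, rtracklayer, vcfR),
  tab-delimited metadata with a per-panel category specification, and a
  byte-round-trippable tab-delimited catalog dialect
  (`STATE("|"EFFECT"|"AA)?("|+")?` cells).
* **Effect annotation** — coding SNVs and indels against one primary
  transcript per gene: synonymous / missense (`T27A`) / nonsense (`W32*`) /
  stop and start loss / frameshift (`R75fs`) / conservative vs disruptive
  in-frame indels (`T2del`) / splice donor–acceptor cores (first and last
  two intron bases), with severity classes (null, modifying, non-modifying)
  and display colors. ANN-style pre-annotated VCFs are accepted as an
  alternative input path.
* **Imputation** — deterministic majority fill of missing genotypes with
  per-call provenance flags rendered `|+` per cell and `+`/`-` per gene row;
  sidecar missingness masks support externally imputed panels.
* **Catalog assembly** — per-gene allele partitions ordered by Total
  descending, categorical frequency tables, and dataset summary statistics
  (genes with only the reference allele, genes with null alleles,
  modifying/null variant counts, per-gene position and allele means).
* **Queries** — gene-id search (with categorical filtering), accession-list
  genotyping for one gene, and per-frequency-cell accession detail.
* **Synthetic panels** — a seeded generator that emits a toy genome, genes
  on both strands, planted variants of every effect class, masked genotypes
  and accession categories, together with a constructively derived
  ground-truth manifest (`verify_against_truth()` checks a built catalog
  against it).

## Worked example

```r
library(allelecat)

fx <- generate_fixture(fixture_spec(seed = 1), file.path(tempdir(), "panel"))
catalog <- build_catalog_from_files(
  fx$files[["fasta"]], fx$files[["gff"]], fx$files[["vcf"]],
  fx$files[["metadata"]], fx$files[["category_spec"]])
catalog
#> <allele_catalog> 24 accessions, 6 genes (5 with modifying positions)
#>   modifying variants: 15 (null: 8); mean alleles/gene: 6.6
```

A per-gene frequency table lists alleles by Total frequency, most frequent
first; category counts never exceed the Total, which also absorbs
uncategorized accessions:

```r
catalog$frequencies[["GENE002"]]
#>    Allele G. soja Landrace Elite Cultivar Total
#> 1       1       3        3     2        2    11
#> 2       2       1        0     1        1     2
#> 3       3       0        1     1        0     2
#> ...
```

Catalog rows carry the genotype state per modifying position, the predicted
effect and compact amino-acid notation for alternate states, `|+` marks on
imputed cells and a `+`/`-` gene-level imputation column:

```r
catalog_rows(catalog, "GENE002")[c(1, 12, 14, 18),
                                 c(1, 2, 8, 9, 10, 11)]
#>  Accession Improvement Status Imputation                chr2:232 ...
#>    ACC0003            G. soja          -                       T
#>    ACC0014              Elite          - C|missense_variant|T39A
#>    ACC0016              Elite          -                       T  (chr2:262 = CT|frameshift_variant|T29fs)
#>    ACC0002            G. soja          -                       T  (chr2:392 = C|splice_donor_variant|)
```

Queries reproduce the two search modes:

```r
res <- search_by_gene_ids(catalog, "GENE002",
                          category_filter = list(`Improvement Status` = "Elite"))
res[["GENE002"]]$frequency   # totals recomputed over Elite accessions only

accession_detail(catalog, "GENE002", 2, "Total")[["Accession"]]
#> [1] "ACC0014" "ACC0022"  # the carriers of the second-most-frequent allele
```

The dataset summary mirrors the catalog-wide statistics:

```r
str(catalog$summary)
#> $ n_genes                   : int 6
#> $ n_genes_reference_only    : int 1
#> $ n_genes_with_null_alleles : int 5
#> $ n_modifying_variants      : int 15
#> $ n_null_variants           : int 8
#> $ mean_alleles_per_gene     : num 6.6
#> $ mean_missing_per_accession: num 0.542
#> ...
```

A command-line wrapper with `simulate`, `build`, `summarize`, `query-genes`,
`query-accessions` and `dump-metadata` subcommands ships at
`inst/cli/allelecat.R` (installed under `system.file("cli", "allelecat.R",
package = "allelecat")`), driven by a JSON run configuration.

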