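---
title: "Gene-level allele cataloging: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level allele cataloging: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelecat)
```

## The problem

Whole-genome re-sequenced germplasm panels expose enormous allelic variation,
but single-variant views (GWAS hits, raw VCF rows) hide how variants combine
within a gene. `allelecat` aggregates a multi-sample VCF to the gene level:
every variant position predicted to *modify* a gene's product is kept, and
each accession's combination of reference/alternate genotype states over
those positions defines its gene-level **allele** — a haplotype class, not a
single nucleotide variant. Alleles are counted by accession category
(e.g. wild relative / landrace / elite breeding material), giving a frequency
table per gene that connects candidate alleles to breeding history and
provenance.

## The pipeline

Stages run in a fixed order:

1. **Read** — FASTA reference, GFF3 gene models, multi-sample VCF, and a
   tab-delimited accession meta-information table. A per-panel category
   specification declares which metadata column forms the primary partition
   (ordered values become frequency-table columns), which columns are
   independent flags, and which are free-form details.
2. **Symbolic-ALT filter** — panels that encode structural indels as `<INS>` /
   `<DEL>` tokens cannot be annotated at sequence level; any record carrying a
   symbolic ALT is dropped whole, and the count is logged. Dropping the whole
   record (rather than the single allele) keeps every kept site fully
   concrete.
3. **Imputation** — missing diploid calls (`./.`) are filled with the site's
   most frequent non-missing genotype; ties break toward the genotype with
   more reference alleles, then lowest allele indices; an all-missing site
   fills homozygous-reference with a warning. Every filled call carries a
   provenance flag that follows it into the catalog (`|+` per cell, `+`/`-`
   per gene row). This deterministic majority rule is the package's own
   imputation stage; the interface also accepts panels imputed by an external
   phasing tool, with original missingness supplied as a sidecar mask so
   provenance is preserved.
4. **Effect annotation** — see below.
5. **Assignment and assembly** — each (site, ALT) pair whose predicted effect
   is `modifying` or `null` joins the variant set of every gene it affects;
   positions sort ascending and multi-allelic sites contribute one catalog
   column whose *state* distinguishes the carried ALT. Accessions with
   identical state vectors form one allele; alleles order by carrier count
   (Total) descending, ties broken by the state vector's lexicographic order,
   so repeat runs are byte-identical. A gene with no modifying positions
   yields exactly one all-reference allele carrying the whole panel.
6. **Tables and summary** — per-gene frequency tables (category counts, flag
   counts, Total including uncategorized carriers) and a dataset summary:
   gene counts (reference-only, with null alleles), modifying/null variant
   counts over distinct (site, ALT) pairs, per-gene position/allele means and
   medians, and mean missing calls per accession.

## Effect model

Effects are computed on one **primary transcript** per gene — the transcript
with the longest total CDS, ties broken by smallest transcript id — because
the catalog reports gene-level alleles, not per-isoform consequences.

Classification order, after trimming the shared prefix/suffix of REF and ALT
to locate the changed interval:

* **Splice cores first.** The first and last two bases of each intron of the
  primary transcript are donor/acceptor cores; any variant whose changed
  interval touches one is a splice-core change. Extended splice regions are
  deliberately out of scope.
* **SNVs** compare reference and alternate codon: same residue — synonymous;
  new stop — nonsense (`W32*` style); lost stop — `*<pos>ext`; a changed
  start codon — `M1?`; otherwise missense (`T27A`).
* **Indels** inside the CDS are frameshifts when the net length change is not
  a multiple of three (`R75fs`, at the first affected residue); otherwise
  in-frame, *conservative* when the changed interval falls on codon
  boundaries and *disruptive* when it spans them (`T2del`, `G3ins`). The
  altered coding sequence is additionally checked for start loss, premature
  stops and stop loss, which take precedence over the plain indel terms.
* Everything outside CDS and splice cores is `non_coding_or_other`.

Severity drives catalog membership. The **null** class (predicted loss of
function) holds nonsense, stop/start loss, frameshift and splice donor/
acceptor changes; **modifying** additionally holds missense and the four
in-frame indel terms; synonymous and non-coding calls are **non-modifying**
and never enter the catalog. Whether stop/start losses belong in the null
class is genuinely open at the margins; they are predicted loss-of-function
here, and the classification is total and deterministic over the vocabulary
so the choice is easy to audit. Display colors follow the catalog's
convention — missense blue, conservative in-frame indels orange, splice
green, other null terms red, everything else white; reference states render
grey at display time. Green takes precedence over red for splice terms so a
front-end can render them distinctly.

A pre-annotated VCF can bypass the internal annotator: `ANN=`-style INFO
entries are mapped onto the same vocabulary (with protein notation converted
from three-letter to compact one-letter form), so catalogs can be built from
panels annotated by an external effect predictor.

## Queries

Two search modes mirror how the catalog is used interactively.
`search_by_gene_ids()` returns, per gene, the frequency table (optionally
recomputed over a categorical subset — alleles with no remaining carrier are
dropped and rows reorder by the recomputed totals) plus catalog rows grouped
by allele, with a 1-based allele index in Total-descending order.
`search_by_accessions_and_gene()` genotypes a request-ordered accession list
for one gene without frequency columns. `accession_detail()` reproduces one
frequency cell: the carriers of allele *k* within one category value, with
per-cell imputation marks — zero-count cells return an empty result.

## The synthetic panel generator

`generate_fixture()` emulates a small inbred re-sequencing panel: a toy
genome (default two chromosomes of 6 kb), six genes alternating strand with
one to three exons, 24 homozygous accessions, and planted variants covering
every supported effect class. Its defaults are the package's declared test
conditions; they are deliberately small enough that every stage can be
verified exactly.

The generator derives ground truth **constructively at plant time**, never by
running the annotator: each planted variant's codon context is pinned (e.g. a
missense is planted as `ACT`→`GCT` at a known codon; a disruptive in-frame
deletion as a three-base deletion spanning pinned codons `AAA`/`CCC`), so the
expected term and notation follow from the construction. Pinned flanking
codons guarantee the emitted REF/ALT normalizes back to the intended
transcript-level change on either strand — an ambiguous indel (one whose
trimmed interval could shift within a repeat) is rejected at plant time
rather than planted. Carrier sets are drawn per site (each site keeps at
least one carrier), category labels are assigned by proportion with the
remainder left uncategorized, and missing calls are masked only at cells the
majority rule provably restores, so post-imputation truth stays exact. The
first gene never receives a modifying variant, keeping a reference-only gene
in every panel.

What the generator does *not* emulate — linkage structure, population
stratification, heterozygosity beyond isolated calls, sequencing error, and
imputation uncertainty — bounds what passing tests show: they demonstrate the
*computation* is exact under known truth, not that majority fill matches a
haplotype-model imputer on real panels.

## Numerical and formatting choices

* Coordinates are 1-based inclusive throughout, matching VCF and GFF3; no
  half-open intervals exist anywhere in the package.
* Heterozygous states render as the allele sequences sorted by allele index
  and joined with `/` (`A/G`); homozygous states as the single sequence. The
  catalog cell grammar is `STATE("|"EFFECT"|"AA)?("|+")?`; effects whose
  notation is empty (splice cores) keep the empty field so cells parse
  unambiguously.
* Missing metadata values render as empty strings, never `NA`.
* Per-gene means and medians in the summary are computed over genes with at
  least one modifying position; reference-only genes would otherwise make
  "alleles per gene" degenerate (every such gene has exactly one allele).
* Tie-breaks (allele order, imputation fill, transcript choice) are all
  total orders, so identical inputs give byte-identical outputs.

## Problem sizes

The shipped tests run the full pipeline on panels of 24 accessions, six
genes and ~18 planted variants across 20 generator seeds, check the
annotator against an independent apply-and-retranslate oracle on 200+
planted variants spanning all effect classes and both strands, and verify
byte-identical round trips of every emitted catalog file. These sizes keep
the whole suite under a minute while exercising every code path; the
pipeline itself is linear in sites × accessions and has no fixed scale
assumptions.

## Known limitations

* One effect per (variant, ALT, gene), on the primary transcript only.
* Upstream/promoter and regulatory effects are out of scope by design.
* The majority-fill imputer ignores linkage; on real panels an external
  imputer plus the sidecar mask is the better path.
* Multi-allelic sites share one catalog column; the original tools' handling
  of such sites is unspecified, and this choice keeps state vectors
  well-defined.
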