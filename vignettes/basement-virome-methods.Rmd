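---
title: "Methods: inferring a basement-fluid virome from scaffolds, counts and chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring a basement-fluid virome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basementvirome)
```

## The setting and the problem

Fluids circulating through the basaltic oceanic crust are hot
(~60–65 °C), anoxic, and chemically distinct from the seawater they
started as. Samples drawn through borehole observatories carry a sparse
microbial community and — as this package helps establish — viruses.
The raw evidence comes in three forms, each needing its own inference
step before a community-level statement can be made:

1. **Metagenome scaffolds** from the > 0.2 µm (cellular) fraction, a
   subset of which a viral-signal detector flags as free viruses
   (categories 1–3) or prophages within host scaffolds (categories 4–6).
   Their taxonomy and hosts must be inferred from protein homology.
2. **Epifluorescence microscopy counts** of stained particles in view
   fields, which must be converted to concentrations and summarized.
3. **Fluid chemistry** (dissolved Mg²⁺), which quantifies how much
   contaminating seawater a sample picked up on its way up the borehole.

## Rank-consensus taxonomic assignment

Every predicted protein on a flagged scaffold is searched against a
viral protein reference. Hits with E > 10⁻⁵ are discarded (the
significance threshold is configurable but this default is the field's
standard for this application), and at most one hit per gene is kept:
lowest E-value, ties broken by higher bit score, then lexicographically
by subject accession, so results never depend on input order.

With a single significant hit the matching virus's affiliation is used
directly. With two or more, the scaffold is assigned to the deepest rank
at which some taxon *t* satisfies both conditions:

* the two hits with the lowest E-values lie under *t*, and
* a strict majority (> 50 %) of all retained hits lie under *t*.

Any taxon passing both conditions must contain the best hit, so passing
taxa form a chain and the deepest winner is unique; the package also
verifies this against a brute-force oracle that tests every node of the
tree (see the test suite). *Majority* is strict: with exactly two hits
both must agree, and two equally supported sibling taxa can never both
win, which resolves ties without arbitrary choices. Unranked
(`no_rank`) taxonomy nodes never terminate an assignment; assignments
land on canonical ranks only.

Statuses: `classified` (consensus at family or deeper on a taxon present
in the reference taxonomy), `unclassified_virus` (deepest support is a
named virus not yet in the reference taxonomy), `undetermined` (no
consensus beyond order), `unknown` (no significant hits). One modelling
choice deserves emphasis: consensus is computed over the *best hit per
protein*, not over all hits, so each gene contributes one vote and
"number of hits" equals "number of proteins with a significant hit".

```{r consensus}
tx <- make_toy_taxonomy()
rank_consensus(best_hit_per_gene(data.frame(
  query_gene = c("g1", "g2"), subject = c("a", "b"),
  subject_taxid = c("s_myo1", "s_sipho1"),
  evalue = c(1e-20, 1e-18), bitscore = c(90, 85))), tx$tree)
```

Two tailed-virus families disagree, so the assignment stops at the order
and is reported `undetermined`.

## Host inference: bins first, consensus second

Host assignment has a strict precedence. A viral scaffold placed in a
genome bin with a taxonomic label takes the bin's lineage, to the lowest
level the bin provides — nothing about its homology hits can change
that. Only unbinned scaffolds (or scaffolds in unlabelled bins) fall
back to consensus over broad-reference protein hits, and then only **to
the domain level**: sub-domain cellular consensus is deliberately not
attempted, because gene-level homology of viral genes to cellular genes
is unreliable below domain. Hits whose subject is itself a virus are
first replaced by that virus's host domain (via a configurable
virus-to-host-domain map); a scaffold with no winning domain whose hits
are all prokaryotic is reported `prokaryote_unresolved` rather than
`unknown`.

For prophage scaffolds classified by both routes, the package reports
the percentage agreement between them and resolves disagreements in
favour of the bin, the more specific and less homology-noise-prone
source. When no scaffold is eligible the agreement is reported
not-applicable rather than zero.

Community composition is summarized by depth-weighted fractions. The
weight is $w_i = \text{depth}_i \times \text{length}_i$, i.e. an
estimate of the reads assembled into the scaffold, because the
scientific claim being made is about the share of *virus-affiliated
reads*, not of scaffolds. A `depth_only` mode is provided for
comparability with coverage-weighted conventions; which convention an
upstream study used is often not recoverable, so both are first-class
and the default is documented here. Fractions are normalized over the
full partition (including `unknown` and `prokaryote_unresolved`) and
must sum to 1.

## CRISPR-bearing scaffolds

CRISPR arrays mark cells with an adaptive-immunity record of past viral
infection, so the host taxonomy of CRISPR-bearing scaffolds profiles
the infected community. Detection is consumed from upstream annotation
(array geometry is validated, never recomputed). Classification is
bin-first as above; unbinned scaffolds are eligible for annotation-based
classification only when at least 2,500 bp long **and** carrying at
least three annotated genes — shorter or sparser scaffolds are
`unknown`, a deliberate floor on evidence. "Annotated" defaults to
"has a taxonomic label" but the predicate is configurable. Eligible
scaffolds get a domain-level consensus over per-gene labels ranked by
score, through the same consensus engine. Summaries report the
unclassified share separately and the archaeal/bacterial shares among
classified scaffolds only, so the two shares sum to 100 % when no other
domain occurs.

## Fluid purity: the two end-member mixing model

Basement fluids lose Mg²⁺ almost completely to water-rock reaction,
while seawater holds ~53 mM, so dissolved magnesium is a conservative
tracer of seawater admixture. A sample is modelled as a linear mixture
of the two end members; the crustal-fluid fraction is

$$f = \frac{\mathrm{Mg}_{sw} - \mathrm{Mg}_{sample}}
           {\mathrm{Mg}_{sw} - \mathrm{Mg}_{crustal}},$$

affine and strictly decreasing in the sample concentration, with
$f(\mathrm{Mg}_{sw}) = 0$ and $f(\mathrm{Mg}_{crustal}) = 1$. Defaults
are 53.0 mM (measured near-bottom seawater) and 2.0 mM for the crustal
end member; the crustal value is an assumption standing in for a
site-specific measured value and both are configurable in
`end_members()`. Values outside the interval clamp with a warning.
Reporting rounds to integer percent; Mg measurements given as a range
are evaluated at both endpoints, yielding a purity range. With these
defaults the packaged samples score 98–100 % crustal fluid.

## Counting statistics

Particle concentrations from view-field counts follow
$c = \bar{k} \cdot (A_{filter}/A_{field}) / V$ with $\bar{k}$ the mean
count per field (typically 20 fields) over the effective filter area
$A_{filter}$ and filtered volume $V$. Summaries use the sample standard
deviation (n − 1 denominator) — the only convention consistent with the
reported dispersion of the packaged sample table — and the coefficient
of variation as SD in percent of the mean. The reporting layer rounds
concentrations to one significant figure, virus-to-cell ratios to two,
and purity to integer percent; full precision is retained internally.
Virus-to-cell ratios are computed only for samples with both counts; the
filtered-only sample (cells removed by 0.2 µm filtration) is excluded
via an explicit flag rather than by its zero count.

```{r fluids}
s <- fluid_abundance_summary(table1_fixture())
report_summary(s$viruses, 1)
report_summary(s$vcr$summary, 2)
```

## Sequence statistics and coordinates

G+C content is computed over unambiguous A/C/G/T only, excluding
ambiguity codes from numerator and denominator alike. Genomic intervals
are fixed to a **1-based, half-open** convention, $[start, end)$ with
length $end - start$: this is the only convention under which the
published prophage coordinates (nt 116,961 to 144,621 of a 540,961-nt
scaffold) reproduce the published 27,660 bp prophage length exactly.
Because GenBank features are 1-based inclusive, `gb_to_halfopen()`
converts. ORF counts in `genome_summary()` are pass-through from
supplied annotations; gene prediction is out of scope.

## The synthetic-data generator

The original metagenome assemblies are not redistributable at package
scale, so validation rests on a seeded generator that emulates the
inputs with planted ground truth. What it emulates:

* scaffolds with log-uniform lengths (2–50 kb) and log-normal mean
  depths (generic assembly-like marginals; both configurable);
* a true host lineage per scaffold, drawn from per-domain taxon mixes
  that mirror the dominant borehole lineages
  (Archaeoglobi-led archaea; Nitrospirae-led bacteria);
* viral scaffolds (default half of 300 scaffolds, matching the order of
  ~150 viral scaffolds per sample in the motivating data) with free
  virus/prophage categories (19 % prophage), and true virus taxa
  consistent with the host domain;
* taxonomically pure genome bins covering half the scaffolds;
* CRISPR arrays on a fifth of cellular scaffolds — the real-data CRISPR
  incidence of a few per thousand scaffolds only materializes at full
  assembly scale, so the rate, not the absolute count, is emulated;
* homology hits with a controllable error model: probability a gene's
  best hit reflects its true lineage, probability of virus-subject
  hits (exercising host substitution), per-gene hit counts, and a
  no-hit probability.

The planted host-domain depth fractions default to 80/20
Archaea/Bacteria, the archaeal-dominated composition the analysis is
designed to resolve. A `weight_matching` mode rescales viral depths so
the planted fractions are *exact*, giving deterministic targets: a
noise-free run must recover 80.0 % archaeal, and the prophage
method-agreement must be 100 %. All draws are fixed by integer seeds and
reruns are byte-identical.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequence-level homology (hits are drawn,
not aligned), chimeric scaffolds and binning errors, uneven gene
density, strain-level diversity within bins, and reference-database
incompleteness beyond a single unclassified-virus clade. Recovery rates
on synthetic data are therefore upper bounds on real-data performance;
the degradation tests (accuracy falling smoothly as hit noise rises)
probe robustness, not absolute accuracy.

## Numerical and design choices

* Deterministic tie-breaking everywhere: E-value, then bit score, then
  accession; output order is ascending E-value. Consensus is
  permutation-invariant by construction and tested.
* With hits spanning domains and no consensus even at domain, the
  assignment is `unknown` with an empty lineage (the corner cannot
  arise in single-domain searches).
* Degenerate inputs error early and loudly: empty summaries, zero
  areas/volumes, identical end members, out-of-bounds intervals,
  taxonomy cycles and orphans. Hit taxids absent from the tree error by
  default; a permissive mode drops them with a warning.
* Undefined ratios (no eligible scaffolds, nothing classified) are
  reported as not-applicable (`NA`), never as 0 or 100.
* Problem sizes in the tests (trees ≤ 50 nodes, ≤ 10 hits, communities
  of 60–300 scaffolds, 1,000 oracle-comparison instances) were chosen as
  the smallest scales at which every code path and boundary is
  exercised; all planted-recovery targets are exact at these sizes, so
  nothing is gained by larger runs.

## Known limitations

* Host inference below domain relies entirely on bins; the package
  cannot refine an unbinned scaffold past domain by design.
* The consensus model weighs genes equally; a scaffold with one
  well-conserved gene and many spurious ones can still be misassigned.
* The mixing model assumes exactly two sources and a conservative
  tracer; any Mg²⁺ uptake or release in the borehole plumbing biases
  purity estimates.
* The statistics of the two deposited complete viral genomes can only
  be validated when their sequences are supplied locally; the package
  ships the machinery, not the sequences.
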