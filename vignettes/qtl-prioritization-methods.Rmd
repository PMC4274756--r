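---
title: "Methods: trait-process association and QTL candidate gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-process association and QTL candidate gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlprio)
```

## The model and its assumptions

A QTL study reports, per trait, one or more genomic intervals. Every gene
overlapping such an interval is a *candidate* for that trait; the causal
gene is hidden among them. `qtlprio` exploits a single biological
assumption: **when a trait maps to multiple QTL regions, those regions
tend to contain genes acting in the same biological process.** Under that
assumption, a Gene Ontology biological-process (BP) term that is
overrepresented among a trait's pooled candidates — and that recurs across
most of the trait's regions — marks the process perturbed by the trait's
causal variation, and the genes annotated with it are the best candidates.

The statistical engine is deliberately plain: for each (trait, term) pair
the one-sided Fisher exact test compares the term's frequency among the
trait's `n` candidates with its genome-wide frequency (`K` of `G` genes),
`p = P(X >= a)` for hypergeometric `X`. We compute this with R's `phyper`,
which evaluates the exact tail; no approximation is involved (the test
suite verifies every table with `G <= 60` against big-integer rational
arithmetic, agreeing to well below 1e-12).

Three design points deserve explanation because the method's behaviour
hinges on them:

* **One pooled BH family.** The Benjamini–Hochberg step-up adjustment is
  applied once to all tested (trait, term) pairs jointly, not per trait.
  Association strength is therefore comparable across traits, and adding
  traits to a compendium changes every q-value — that is intended: the
  compendium is analysed as one experiment.
* **Generality filter before testing.** Terms annotated to too large a
  fraction of the genome ("response to stimulus"-sized catch-alls) are
  uninformative for pinpointing genes. They are removed *before* testing,
  so they never inflate the multiple-testing burden. The default cap is
  1% of genome genes, compared strictly (`<`); the comparator is
  configurable (`generality_cmp = "le"`) because "less than 1%" and "not
  higher than 1%" are both defensible readings of the operating point.
* **Region-occurrence filter after testing.** A term carried by many genes
  of a single large region can be statistically enriched without any
  cross-region support — exactly the signal the core assumption says to
  distrust. Associated terms must occur (through at least one gene) in at
  least half of the trait's retained regions. This is a filter on the
  *interpretation* of a test, so it sits after the correction and does not
  change the testing family.

Pairs with zero annotated candidates (`a = 0`) are not tested by default:
their p-value is 1 and they carry no evidence, but they would enlarge the
BH family. Because a different choice here changes all q-values,
`include_zero_counts = TRUE` restores them for sensitivity analysis.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `fdr_threshold` | 0.1 | BH cutoff, inclusive (`q <= 0.1`) |
| `min_region_fraction` | 0.5 | minimum fraction of a trait's retained regions containing the term, inclusive |
| `max_generality` | 0.01 | maximum fraction of genome genes annotated with a tested term, strict |
| `max_region_genes` | 450 | genes per region; larger regions are excluded (450 itself is retained) |
| `permutation_iters` | 1000 | iterations for all permutation tests |
| `overlap_rule` | `"any"` | gene–region membership: one shared base suffices; `"contained"` requires the gene span inside the region |
| `p_estimator` | `"count"` | empirical p = count/iters; zero counts reported as `< 1/iters`; `"add_one"` gives (count+1)/(iters+1) |

The first four defaults are the published operating point of the method;
the region cap exists because very gene-rich regions swamp the candidate
pool of their trait while carrying almost no positional information. The
Fisher background `G` counts **all** genes in the gene-model file,
including unannotated ones — the original analysis kept unannotated genes
in its background — with `annotated_only_background = TRUE` as a
sensitivity option.

`parameter_sweep()` re-runs the full pipeline over a grid of the three
thresholds and scores each point by recall of a reference gene set, the
prioritized fraction, and the permutation p-value — the procedure by which
the defaults were originally chosen. Relaxing `max_generality` admits more
terms and monotonically enlarges the prioritized set on clean fixtures;
pushing `min_region_fraction` towards 1 eventually destroys recall, since
real and planted signals rarely cover every region.

## Coordinate and identifier conventions

Internal coordinates are 1-based inclusive (GFF3 convention); BED input is
converted on read (`start + 1`, `end`), and the converted gene length
equals the BED `end − start`. Strand is stored but ignored everywhere:
interval overlap and SNP distance are strand-free notions here. Trait
names are opaque strings matched exactly; cross-study trait matching is a
curation task, not something this package guesses at. External gene
identifiers are mapped through an explicit two-column table
(`apply_id_mapping()`), and unmapped identifiers are returned to the
caller rather than dropped.

## Degenerate inputs and numerical choices

* Empty regions are legal and retained by the size filter (vacuously under
  the cap); traits whose regions are all excluded are dropped and
  reported, never silently.
* `fisher_one_sided()` rejects count combinations violating
  `max(0, n+K−G) <= a <= min(n, K)` instead of returning garbage.
* BH inputs outside [0, 1] are an error; an empty p-vector yields an empty
  result.
* The SNP–gene distance is 0 inside the gene span, else the distance to
  the nearer span edge (transcription start sites are not modelled; gene
  models in compendium-scale annotations are too heterogeneous for TSS
  semantics to be trustworthy). Ties are broken by (distance, gene id) so
  neighborhoods are deterministic.
* Empirical permutation p-values use the plain count estimator to match
  the "how many random folds did at least as well" definition; a zero
  count is reported as `< 1/n_iter` rather than 0 being presented as an
  achieved significance level.
* All outputs are sorted on stable keys, and every stochastic operation is
  a pure function of (inputs, seed), so identical runs are byte-identical.

## The annotation-randomization null

`randomize_annotations()` permutes gene identities over whole annotation
*bundles*: gene *i* receives gene π(*i*)'s complete term set for a uniform
random permutation π of the gene universe. Both margins of the gene×term
incidence matrix — each term's genome count and the multiset of per-gene
annotation counts — are preserved exactly, so the null keeps the
annotation's size structure while destroying any gene-position linkage.
`run_prioritization(..., null_run = TRUE)` runs the identical pipeline on
such a randomization and produces the same output schema, making the
negative control a first-class run mode.

## What the synthetic generator emulates — and what it does not

`simulate_qtl_study()` builds a genome of uniformly tiled genes (default
2 chromosomes × 500 genes of 1 kb with 1 kb gaps), 50 BP terms, and 5
traits with 4 non-overlapping 20-gene QTL regions each. Background term
sizes follow a truncated power law (exponent 1.5, minimum 2 genes, cap 5%
of the genome, rescaled to ~1 annotation per gene), mirroring the
long-tailed size distribution of real GO usage at desk scale; background
annotations are assigned independently of genomic position, so *any*
positional enrichment is attributable to the planted signal — this is what
makes the generator a clean oracle. Each trait owns one causal term: every
planted region receives 2 genes annotated with it, plus one background
carrier placed outside the trait's regions, keeping the term's genome
count (9/1000) strictly under the 1% eligibility cap. Setting
`causal_background_genes` above the cap makes a planted term ineligible on
purpose; lowering `f_regions` below `min_region_fraction` makes it fail
the occurrence filter by construction. SNPs sit at midpoints of planted
genes and the fine-map reference is a random half of them.

These conditions are scaled down from a real compendium by roughly a
factor of 40 in genome size, and they are *cleaner* than real data in
ways that matter for interpreting green tests: gene density is uniform
(real genomes cluster genes); annotations are complete and error-free
(real BP predictions are noisy and biased towards well-studied genes);
regions within a trait never overlap and all have equal size; trait names
match across files exactly; and there is no GO-hierarchy redundancy among
terms, because input annotations are taken as given and not
ancestor-closed. Passing tests therefore demonstrate the *machinery* —
counting, testing, filtering, permutation calibration — not robustness to
annotation noise or to correlated terms.

## Problem sizes used by the test suite

The suite verifies the Fisher tail exhaustively for all tables up to
`G = 60` (~635,000 tables), BH on 1,000 random vectors up to length 500,
planted-signal recovery and the randomization null over 50 generator
seeds at the default configuration, permutation-test calibration with 200
replicates of 500 iterations, and neighborhood queries against brute
force on 100 random instances. These sizes were chosen to make the checks
statistically decisive at desk scale.

## Known limitations

* The method selects, it does not rank: all genes carrying an associated
  term are reported equally. Within-region uniqueness
  (`single_annotated_gene_regions()`) is the only sharpening offered.
* GO hierarchy is ignored; a parent and child term are separate tests. If
  the input annotation is ancestor-closed, general parents are usually
  removed by the generality filter, but sibling redundancy remains.
* Traits mapped to a single QTL region pass the occurrence filter
  trivially (1/1), so for them the method degenerates to plain enrichment.
* LOD scores and interval confidence are not used; every region counts
  equally.
* The permutation null draws per-trait gene sets independently, so a gene
  shared between two traits can be drawn for both — matching how the
  observed prioritized sets behave, but meaning the null is not a
  permutation of a single pooled set.
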