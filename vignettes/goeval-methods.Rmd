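---
title: "Methods: task-based evaluation of GO snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-based evaluation of GO snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goeval)
```

## The evaluation model

`goeval` treats the GO knowledgebase — an ontology structure paired with an
annotation corpus — as an instrument, and scores the instrument by how well
it recovers a known biological signal in the analysis it is most used for.
The procedure:

1. Choose one or more terms of interest whose enrichment is expected *a
   priori* in a chosen dataset (a positive control grounded in biology, not
   in the knowledgebase itself).
2. Derive a study gene list from the dataset with fixed, conventional
   statistics (below).
3. Build each term's gene set by propagating direct annotations up the
   ontology (true-path rule) and applying a term-size filter.
4. Run a one-sided Fisher's exact over-representation test for every term,
   Bonferroni-correct, and rank.
5. Read off the rank and p-value of the terms of interest.

Repeating step 3–5 with the ontology and annotations sampled at successive
release dates yields a per-term trajectory; the significance of the term of
interest over time is the performance curve of the knowledgebase for that
biological context. Because a snapshot is a *pair*, the two components can
be decoupled: `decouple(snapshots, "fix_annotations", ref)` lets only the
structure vary, `"fix_structure"` lets only the annotations vary, and the
contrast between the two trajectory families attributes changes to one
component or the other.

Assumptions worth stating: the study gene list is computed **once** and
reused across snapshots — the framework evaluates the knowledgebase, not the
differential-expression call, and recomputing the list per year would
confound the two. Term identity across snapshots is keyed by the canonical
id, with per-snapshot `alt_id` resolution, so merged terms line up across
eras; a term with no gene set in a snapshot is an explicit absence
(`absent_from_snapshot`), never a silent gap. The Bonferroni multiplier `m`
is the number of terms actually tested in each snapshot, since
size-filtered terms yield no p-value.

## Statistical components and their defaults

**Probe filter.** The global median *M* is taken over every cell of the
probe-by-sample grid (not per-probe summaries; for even counts, the midpoint
of the two central order statistics, R's default). A probe is removed when
`max(row) < M` — strictly, so a probe whose maximum ties the median is kept.
Filtering precedes the log transform.

**Log transform.** Natural logarithm of every value. Non-positive values
are an error unless a positive clipping floor is configured (microarray
intensity summaries are positive; a floor is only needed for preprocessed
inputs with zeros).

**Differential expression.** Independent two-sample t-test per probe,
two-sided, pooled-variance (Student) by default with Welch behind
`var_equal = FALSE` — "independent t-test" canonically reads as the pooled
form. `n_tests` for the Bonferroni correction is the number of probes that
survived the filter. A probe with zero variance in both groups and equal
means carries `p = 1` (no evidence, not an error). Gene-level significance
uses the best-probe rule (any significant probe makes its gene DE) with
`all_probes` as the stricter alternative; the mapping from probes to genes
is a user-supplied two-column table.

**Propagation.** Ancestors are computed over `is_a` + `part_of` by default
— the classical true-path relation set across the 2004–2012 era;
`regulates` edges (introduced 2008) are parsed and can be added to the
relation set, but regulation is not parthood, so they are off by default.
The closure is reflexive: a gene annotated to a term belongs to that term's
set. Cross-namespace parent edges are rejected at parse time; GO does not
use them in the formats covered here.

**Annotation filters.** Filters compose conjunctively: date cutoff
(`date <= max_date`, ties included — the cutoff reconstructs the corpus *as
of* that date), evidence-code exclusion (IEA annotations are **kept** by
default; their blanket exclusion is a legacy convention, and dropping them
is a one-flag experiment), `NOT`-qualifier removal (on by default: a negated
annotation argues against membership), and aspect restriction (default `P`,
biological process). Identical gene–term pairs arising from multiple
evidence lines count once in gene sets.

**Term-size filter.** Inclusive bounds, 3–500 genes by default. The filter
is applied *after* intersecting sets with the measured-gene universe
(`restrict_to`), so the Fisher table is consistent: every count in it refers
to genes that could actually have appeared in the study list. Counting
sizes over all annotated genes instead is available by omitting
`restrict_to`.

**Enrichment.** `fisher_pvalue(k, K, n, N)` sums the hypergeometric upper
tail in log space (`lchoose`), stable for universes beyond 1e5 genes. Ties
in raw p are ranked by lexicographic term id, making ranks deterministic.
The one-sided upper tail is the field's standard reading of "Fisher's exact
enrichment"; a two-sided variant was deliberately not added — it answers a
different question (any deviation, including depletion).

**Trajectory omission rule.** `track_terms()` masks cells with `p_raw = 1`
(reason `p_equals_1`) or gene-set size below 3 (`fewer_than_min_genes`) and
drops terms absent everywhere; when both conditions hold, the size reason is
recorded, as the emptier description of the cell.

## The synthetic study corpus

The generator stands in for the real inputs (a GEO expression dataset plus
archived GO/GOA releases) so that every stage is testable offline:

- **Ontology**: a rooted DAG, acyclic by construction — terms are placed on
  levels whose sizes grow geometrically (`branching`, default 3) down to
  `max_depth` (default 6), and each non-root term draws 1–2 parents from
  strictly shallower levels, 80% `is_a` / 20% `part_of`.
- **Annotations**: each of `n_genes` (default 500) genes gets
  `max(1, Poisson(2))` direct annotations to uniformly chosen terms, dates
  uniform over 2003–2012 so date filters are exercisable, evidence codes
  IEA/IDA/TAS at 0.5/0.3/0.2.
- **Growth**: snapshots are nested record subsets at fractions 0.2–1.0 of
  the full corpus (exact sizes, seed-fixed order). Subsetting records rather
  than filtering dates keeps snapshot sizes exact; the date mechanism is
  tested separately where it is the subject.
- **Expression**: one probe per gene; controls draw
  `exp(baseline + N(0, σ))` with baseline 6 and σ = 0.5 on the ln scale;
  case samples of genes in the planted term's propagated set gain a ln-scale
  shift δ = 2 with 10 samples per group. Simulating on the natural scale by
  exponentiation means the standard pipeline — including the positivity
  precondition of the log step — runs verbatim. The planted term is chosen
  as the term whose propagated set size is closest to 25 within [10, 100]:
  large enough to clear the size filter, small enough to be specific.

These defaults are the conditions the test suite and `scripts/acceptance.R`
run under (100 and 20 replicates respectively for rank-1 recovery; 10
replicates for null calibration and growth monotonicity — sizes at which
each run takes well under a second). What the generator does **not**
emulate: the power-law term-size distribution of real GO, annotation bias
toward well-studied genes, probe-level noise structure (multiple probes per
gene, cross-hybridization), evidence-code correlation with date, and term
obsolescence/merging over time (alt-id drift is exercised by hand-built
fixtures instead). Passing tests therefore demonstrate the machinery's
correctness and the framework's internal logic, not performance claims about
real GO releases.

## Numerical and degenerate-input choices

- Hypergeometric tails are exact sums of `exp(lchoose(...))` terms; each
  term is ≤ 1 so the sum cannot overflow, and underflow merely rounds a
  vanishing tail to 0. Tail at `k = 0` is exactly 1 by construction.
- An empty study∩universe intersection is legal (all `k = 0`, `p = 1`); an
  empty or all-filtered collection in a series becomes an all-absent
  trajectory column with a warning rather than an error, because cross-era
  runs legitimately produce them.
- OBO/GAF parsing is strict on structure (cycles, dangling parents,
  duplicate stanzas are hard errors naming the culprit) but tolerant on
  content by default (malformed GAF lines are collected into a parse report;
  `strict = TRUE` escalates).
- All generators are deterministic in their seed and restore the caller's
  RNG state; a fixed seed yields byte-identical OBO/GAF serializations.

## Limitations

The framework measures performance *for a chosen biological context*; it
says nothing about the knowledgebase as a whole. Reproducing published
historical numbers additionally depends on choices the original analyses
leave undocumented — probe-to-gene mapping version, the exact May release
dates, the t-test variant, and the background universe — so external-data
checks should be read as consistency targets rather than exact oracles. No
GSEA-style, parent–child, or FDR-based procedures are included: the
evaluation statistic is deliberately the plain Fisher/Bonferroni pipeline
whose behavior over snapshots is being measured.
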