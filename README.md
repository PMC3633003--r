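# goeval — task-based evaluation of Gene Ontology knowledgebase snapshots

The Gene Ontology (GO) and its annotation corpus (GOA) change continuously:
terms are added, merged and made obsolete, and annotations accumulate. Most
assessments of that knowledgebase rely on ad-hoc structural or coverage
metrics. `goeval` instead measures the knowledgebase by the task it is most
used for: **gene-set over-representation analysis**. Given a biological
context where the expected answer is known (e.g. a term *T* that should be
enriched in a particular dataset), the framework asks how significant and how
highly ranked *T* is when the analysis is run with a given (ontology
structure, annotation set) pair — and how that readout changes across
time-stamped snapshots of the knowledgebase.

The package is aimed at curators, tool builders and bioinformaticians who
want to quantify whether ontology or annotation changes improved real
analyses, or to benchmark alternative (e.g. text-mined) annotation sets by
injecting them as snapshots.

## The statistic at the core

For a study gene list *S* (differentially expressed genes) drawn from a
universe of *N* analyzable genes, and a term with *K* annotated genes (after
true-path propagation), the over-representation p-value is the upper tail of
the hypergeometric distribution — the one-sided Fisher's exact test:

    p = P(X >= k),   X ~ Hypergeometric(N, K, n),   k = |S ∩ term set|

with *n* = |S ∩ universe|. P-values are Bonferroni-corrected over the *m*
terms tested (`min(1, m·p)`), and terms are ranked by ascending raw p with
lexicographic term-id tie-breaks. The framework readout for a term of
interest is its rank and p-value per snapshot, assembled into a trajectory
table; a decoupling experiment freezes either the ontology structure or the
annotation set at a reference snapshot to attribute trajectory changes to
the other component.

The surrounding pipeline follows the standard microarray recipe: probes
whose maximum value across samples falls below the grid-wide median are
removed, values are natural-log transformed, a pooled-variance two-sample
t-test is run per probe, and a gene is differentially expressed when any of
its probes has Bonferroni-corrected p < 0.05. Term sets annotated to fewer
than 3 or more than 500 genes are excluded from enrichment.

## Worked example

```r
library(goeval)

study <- simulate_study(simulation_config(seed = 1))
m  <- log_transform(filter_probes(study$expr))
de <- differential_expression(m)
de
#> de_result: 500 probes tested, 25 DE genes at Bonferroni alpha 0.05 (0 unmapped probes)

coll <- filter_by_size(study$collection,
                       restrict_to = unname(study$expr$probe_gene_map))
res <- enrich(de$de_genes, coll)
head(as.data.frame(res), 3)
#>      term_id          term_name  k  K  n   N        p_raw   p_adjusted rank
#> 1 GO:0000052  synthetic term 52 25 25 25 500 9.579343e-43 1.743441e-40    1
#> 2 GO:0000018  synthetic term 18 25 39 25 500 1.444996e-32 2.629894e-30    2
#> 3 GO:0000129 synthetic term 129  8  8 25 500 1.181028e-11 2.149471e-09    3

tr <- run_series(study$snapshots, de$de_genes, study$planted_term,
                 series_config(restrict_to = unname(study$expr$probe_gene_map)))
as.data.frame(tr)
#>      term_id snapshot status rank        p_raw   p_adjusted set_size
#> 1 GO:0000052       t1 tested    1 5.858599e-05 3.983847e-03        3
#> 2 GO:0000052       t2 tested    1 3.692161e-14 4.209063e-12        9
#> 3 GO:0000052       t3 tested    1 1.142379e-25 1.656450e-23       17
#> 4 GO:0000052       t4 tested    1 2.484902e-29 4.100089e-27       19
#> 5 GO:0000052       t5 tested    1 9.579343e-43 1.743441e-40       25
```

The planted term `GO:0000052` (the simulated analogue of a context term like
*angiogenesis* in a glioblastoma dataset) is recovered at rank 1, and its
p-value falls by nearly 40 orders of magnitude as the annotation corpus grows
from 20% to 100% of its records across the five snapshots — the enrichment
signal strengthening purely through annotation accrual, the structure being
frozen. `decouple(snapshots, "fix_annotations", ref)` flattens the
trajectory, confirming the attribution.

Real data enter through `parse_obo()`, `parse_gaf()` (with
`filter_annotations()` for evidence/date/qualifier/aspect rules) and
`parse_matrix()` (plain TSV or GEO GDS SOFT dialect); `read_manifest()`
loads a labelled series of OBO/GAF snapshot files. A command-line wrapper
with subcommands `de`, `enrich`, `series`, `decouple` and `simulate` is at
`inst/cli/goeval.R`.

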