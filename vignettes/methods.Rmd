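---
title: "Methods: expression calls, scores and condition-graph integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression calls, scores and condition-graph integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoexpress)
```

## The problem

Transcriptomics experiments are annotated with wildly heterogeneous
vocabularies, and their count matrices cannot be naively merged: batch
effects are confounded with the biology of interest (species, sex,
tissue), and removing one removes the other. `ontoexpress` therefore
never integrates count matrices across experiments. Instead it reduces
every sample to two summaries that are comparable across experiments,
protocols and data types, and integrates those:

* a **present/absent expression call** per gene and condition — a
  qualitative statement that the gene's signal exceeds the background
  noise of the experiment; and
* an **expression score** in (0, 100] per gene and condition — a
  nonparametric summary of expression level derived from within-sample
  ranks, with 100 the top expressed gene of a condition.

Both are attached to **post-composed conditions** — tuples of
(anatomical entity, cell type, developmental stage, sex, strain,
species) — and propagated along a **condition graph** ordered by
ontology ancestry, so that data annotated to a fine cell population in a
brain substructure also inform queries about, say, all glial cells of
the adult brain.

## Conditions and the condition graph

Each axis has its own vocabulary: anatomy and cell type come from DAG
ontologies traversed over `is_a` and `part_of`; developmental stages
from a stage ontology (the traversed relation set is a parameter,
`stage_relations`, because stage ontologies are sometimes navigable over
`is_a` only); sex and strain from flat controlled vocabularies whose
every member hangs directly under the root ("any sex", "wild type").
The cell type and the anatomical structure are deliberately kept as two
separate fields rather than requesting pre-composed intersection terms:
pre-composing every pair used in annotations would inflate the ontology
and stall curation. The verbatim author label of every sample is also
retained (`free_text_label`), because mapping free text to an ontology
term can lose precision — two author cell types may map to the same
term.

A condition `c1` is an ancestor of `c2` when it is ancestor-or-equal on
*every* axis — the product order of the five axis orders. The condition
graph contains the annotated conditions plus every inferred ancestor
combination. Two representation choices matter:

* **Edges** are stored as the transitive reduction. In a product of
  partial orders, a covering step changes exactly one axis by one
  covering step of that axis, which is how edges are enumerated.
* **Reachability** (which samples feed which condition) is answered
  from per-annotation ancestor indexes, not from the edge list, because
  ancestor products grow combinatorially. `build_condition_graph` caps
  the node count (`max_nodes`, default 10^6) and fails loudly rather
  than exhausting memory.

Multispecies ontologies carry **taxon constraints** — per-species
existence flags. The default is strict: a (term, species) pair absent
from the table counts as non-existent, which is the safe reading for
curation; a `permissive` flag inverts this. When filtering an ontology
to one species, children of removed terms are re-wired to every nearest
retained ancestor, preserving reachability among surviving terms.

## Present/absent calls

The null model for "not expressed" is the distribution of abundances of
**intergenic regions** — genome regions free of annotated genes —
measured in the same sample. The call procedure:

1. **Reference selection.** Some intergenic regions behave like genes
   (unannotated transcription) and must not define the null. Bulk data
   are used to screen them. The default rule is a robust outlier screen
   on the regions themselves: discard a region when its mean
   log2(abundance+1) across bulk samples exceeds the median of region
   means by more than `k` MADs (default `k = 4`). The rationale for
   this choice over a rule anchored on the genic distribution is
   calibration: any rule that truncates the upper tail of the *clean*
   intergenic distribution makes the empirical p-values
   anti-conservative, because genes are then compared against a
   background that is systematically lower than the true noise floor.
   The MAD screen retains the clean noise distribution essentially in
   full while discarding gene-like outliers, which in the synthetic
   scenario removes well over 90% of planted dubious regions. A
   `genic_quantile` rule (discard above the q-th percentile of genic
   means, default q = 5) is provided as an alternative; it is
   appropriate when the genic table contains only robustly expressed
   genes.
2. **Per-sample p-value.** For gene *g* in sample *s* with *n*
   reference regions, `p = (k + 1) / (n + 1)` where *k* counts
   reference regions with abundance at or above the gene's (ties count
   toward *k*, the conservative direction). The add-one correction
   guarantees `p` in (0, 1] and a super-uniform null
   (`P(p <= a) <= a + 2/(n+1)`), verified by simulation in the test
   suite. A gene at zero abundance gets `p = 1` by the tie rule and can
   still yield an absent call — intended.
3. **Pseudo-bulking.** Droplet single-cell libraries are reduced to one
   bulk-like sample per author-annotated cell population by summing the
   raw reads of its cells (the authors' clusters are taken as given —
   the data are never re-clustered). Summed counts are CPM-normalized
   over all features (genes and intergenic regions together), after
   which the sample is treated exactly like a bulk sample. Per-gene raw
   counts over assigned barcodes are conserved exactly, a property
   tested as integer equality.
4. **Integration.** All per-sample p-values of a gene available in a
   condition *and its graph descendants* are combined into one p-value
   per gene and condition. The default combiner is Fisher's method;
   Stouffer and a best-BH-adjusted-p combiner (`min_i p_(i)·k/i`) are
   also provided. Samples are weighted equally regardless of data type.
5. **Classification.** Present iff the integrated p-value is at most
   `alpha` (default 0.05). Quality tiers are documented stand-ins
   (production databases expose confidence levels without publishing
   their definition): *gold* — at least two contributing samples
   individually significant; *silver* — significant on the integrated
   p-value only; absent calls in `(alpha, 2*alpha]` are *bronze*
   (borderline), other absent calls gold/silver by the analogous count
   of non-significant samples.

## Expression scores

1. Genes are ranked within each sample by decreasing abundance
   (fractional ranks; tied abundances share the mean of their tied
   positions). Only the sample's *detectable* genes are ranked — a
   polyA protocol cannot measure non-polyadenylated transcripts, so its
   rank scale is shorter. The sample's `max_rank` is its
   detectable-gene count; for droplet pseudo-bulk samples the
   detectable set is the gene complement of the count matrix.
2. Ranks are normalized across protocols by proportional stretching,
   `r * global_max / sample_max`, with `global_max` the largest sample
   `max_rank` of the species (per-data-type normalization is a config
   option, off by default).
3. A gene's normalized ranks over a condition and its graph descendants
   are averaged (unweighted; a production system may weight by data
   type — a documented divergence).
4. The mean rank is inverted onto the score scale:
   `score = 100 * (M + 1 - mean_rank) / M`, with `M` the condition's
   rank scale. The formula is chosen so the endpoints have clean
   semantics: rank 1 maps to exactly 100 (the top expressed gene of a
   condition scores 100, attained), and the bottom rank maps to
   `100/M > 0`, so 0 is open. Within a sample, score order equals
   abundance order, and scores are invariant to rescaling all
   abundances by a positive constant.

## Enrichment

`topanat()` tests a gene list for over-representation of anatomy and
cell-type terms, with genes mapped to terms by their present calls
(each gene attaches to its call's anatomy and cell-type terms and all
their ancestors). The test is the exact upper-tail hypergeometric. The
DAG is decorrelated with the **elim** scheme — the simplest published
topGO-family method: terms are processed leaves-upward and the genes of
any term significant at `elim_threshold` (default 0.01, applied to the
raw p before FDR) are removed from its ancestors before those are
tested, so a nested signal is reported at its most specific term.
`classic` mode (independent tests) is kept for oracle testing. Terms
with fewer than 2 background genes are untestable and skipped. The
default background is every gene with at least one present call; a
genome-wide universe can be supplied instead when a gene universe file
is available — both are offered because "all genes in the genome" is
only testable with such a file.

## The synthetic-data generator

`simulate_bundle()` emulates the data model the pipeline consumes, with
known ground truth. Its defaults are the generator's study conditions,
fixed once:

* 2000 genes, 1000 intergenic regions of which 100 planted dubious;
* intergenic noise floor: log-normal, sd 1 on the log2 scale, median 1;
* expressed genes and dubious regions at `effect_size = 8` times the
  reference median;
* half the genes expressed somewhere; each expressed gene is expressed
  in a random half of the annotated conditions (at least one);
* a replicated design: 12 bulk libraries over 6 annotated conditions
  (2 each) and 2 droplet libraries (200 cells, 4 author clusters,
  5000 reads per cell) annotating the same 4 cell populations, with
  cluster expression profiles redrawn per library. Replication was
  fixed as the default because integrating unreplicated conditions is
  neither what curated databases do nor statistically comfortable: a
  single sample bounds sensitivity at whatever one empirical p-value
  can deliver, while two independent samples combined by Fisher's
  method recover planted signal at the 8-fold effect size with
  sensitivity above 0.98 in the test suite;
* balanced toy ontologies (depth 2, branching 2) for anatomy and cell
  type, a stage chain, and standard sex/strain vocabularies;
* one RNG stream per component (ontologies/annotations, truth, bulk
  abundances, single cell), derived from the seed by fixed offsets, so
  changing one knob does not shift the other components' draws.

Single-cell counts are multinomial per cell from the cluster's profile
over genes *and* intergenic regions — intergenic features are
quantified in every library, which is what makes the intergenic null
applicable to pseudo-bulk samples.

What the generator does *not* emulate: over-dispersion beyond the
log-normal profile noise, ambient RNA and doublets, protocol-specific
gene-length or GC biases, correlated co-expression modules, and
incomplete taxon constraints. Passing recovery tests on this generator
therefore demonstrates that the machinery is calibrated and recovers
cleanly separated signal; it does not certify performance on real
droplet data, where the null and the signal are closer.

## Numerical choices and degenerate inputs

* Ties at equal abundance count toward `k` in the p-value (larger p,
  conservative) and share mean ranks in the score.
* `p = (k+1)/(n+1)` never returns 0, so Fisher's statistic is always
  finite; `p = 1` contributes 0 to the statistic.
* The reference must contain at least 10 regions measured in the
  sample; fewer is an error, never a silent fallback.
* Conditions sharing an identical contributing-sample set are computed
  once (group vectorization); results are identical to the per-pair
  scalar operations, which the tests check.
* All-zero samples rank every gene at the mean rank and give `p = 1`
  everywhere — they contribute absent calls, not errors.
* Output files are deterministically ordered (gene, then condition
  key) and numerics are written with 12 significant digits, so reruns
  are byte-identical.

## Problem sizes

The shipped test-suite and acceptance scenarios use desk-scale sizes
chosen to exercise every code path with comfortable margins: the
recovery scenario is the generator's default (2000 genes, 1000 regions,
10 annotated conditions, 16 samples, ~180 graph nodes); the score-range
scenario uses 5000 genes over 20 bulk conditions; calibration uses 2000
null genes against 1000 reference regions. Each completes in seconds.

## Known limitations

* The exact production definitions of the call combiner and of the
  quality tiers are unpublished; the defaults here are documented
  stand-ins and flagged as such in output headers.
* Whether full-length single-cell protocols should be pseudo-bulked or
  called per cell is not settled; all single-cell data are pseudo-bulked
  uniformly here.
* H5AD input is not implemented; the MTX triplet is the single-cell
  path (the format schema is self-documented, not byte-compatible with
  any production database's download files).
* Cross-species comparison is limited to conditions expressed in the
  shared ontology after taxon-constraint filtering; no statistical test
  is offered on scores.

## A worked example

```{r example}
sim <- simulate_bundle(synth_config(seed = 1))
res <- run_pipeline(sim$bundle)
rec <- evaluate_recovery(res$calls, sim$truth, res$graph)
round(c(sensitivity = rec$sensitivity,
        false_present_rate = rec$false_present_rate), 3)
head(res$calls[res$calls$state == "present",
               c("gene_id", "anat", "cell_type", "p_integrated",
                 "quality", "score")], 5)
```
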