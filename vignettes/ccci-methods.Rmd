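---
title: "Methods: assembling and analysing a cilia/centrosome interactome"
author: "cccinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and analysing a cilia/centrosome interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccinet)
```

`cccinet` studies the cilia/centrosome proteome as a gene–gene interaction
network. This vignette documents the models and procedures each stage
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic benchmark does and does
not establish.

## 1. Evidence integration

Interaction support arrives as independent *channels* — genomic context,
high-throughput experiments, co-expression, prior knowledge — each a score
in $[0,1]$. Channels are combined under the standard probabilistic-union
convention used by interaction databases: every channel is first corrected
for the prior probability $p$ that a random pair interacts,

$$s_i' = \max\!\left(0,\ \frac{s_i - p}{1 - p}\right),$$

the corrected scores are combined as $c' = 1 - \prod_i (1 - s_i')$, and the
prior is restored: $c = c'(1-p) + p$ (0 when no channel exceeds the prior).
This makes the combination monotone in every channel and invariant to
channel order, and excluding a channel can only lower the result.

Choices worth noting:

* **Prior `prior = 0.041`.** The prior is not dictated by the analysis that
  motivated this package, so it is exposed as configuration with the
  conventional default; results are insensitive to it for the synthetic
  benchmark because planted scores sit well above it.
* **Channel exclusion happens before combination**, after per-channel
  correction. Excluding text-mining-like channels before the union is the
  standard reading; the alternative (recompute the prior too) changes
  nothing qualitative and is not offered.
* **Cutoff `cutoff = 0.7` with `>=` semantics.** A score exactly at the
  cutoff is kept. 0.7 is the conventional "high confidence" threshold.
* **Duplicate or non-canonical pairs are errors**, not silently merged:
  evidence tables must list each unordered pair once as
  `gene_a < gene_b`. Surfacing data problems early beats guessing.

Genes of the universe without any passing edge are reported as singletons
and removed before downstream analysis. Connected components are labelled
largest-first with ties broken by the smallest member id, so labels are
reproducible. The scale-free check fits $\log_{10} f(k)$ on $\log_{10} k$
by ordinary least squares over observed degrees — the convention of
Cytoscape-style network analyzers, chosen for comparability — with a
discrete maximum-likelihood (Hill) estimate available via `method = "ml"`.
Fewer than three distinct degrees leaves the exponent undefined rather than
fitting a line through two points.

## 2. MCODE community detection

The Molecular Complex Detection algorithm is implemented from scratch
because it is the analytical core of the pipeline (no maintained R
implementation exists, and the reference implementations are
order-dependent).

* **Vertex weighting**: weight $= k_{\max} \times$ density of the highest
  k-core of the vertex's closed neighborhood; vertices below
  `degree_cutoff = 2` weigh 0. The k-core machinery uses
  `igraph::coreness`; the test suite certifies the weights against a
  brute-force enumerator of all neighborhood subgraphs on every connected
  graph with at most 7 vertices.
* **Prediction**: seeds are visited in decreasing weight; a breadth-first
  expansion adds unassigned neighbors with weight
  $\ge w_{seed}(1 - \texttt{node\_score\_cutoff})$, to `max_depth = 100`
  levels; each vertex joins at most one complex.
* **Post-processing**: complexes without a 2-core are discarded
  (`k_core = 2`); `haircut = TRUE` iteratively strips degree-1 members
  (equivalently, takes the 2-core); `fluff = FALSE` by default — when on,
  boundary vertices with closed-neighborhood density above `fluff_cutoff`
  are added and may be shared. The complex score is density × size, and
  communities are renumbered by descending score.

Numerical/tie-break decisions: all ties — seed order, expansion order,
community ranking — break lexicographically by gene id. The original
algorithm is input-order-dependent; determinism was preferred over fidelity
to an unspecified iteration order, and a test verifies invariance to edge
row order. One behavioural consequence of the published expansion rule is
worth recording: two equally dense cliques joined by a single bridge edge
merge into one complex when all vertex weights tie (the bridge endpoint
passes the seed-relative threshold), and the haircut does not separate them
because no member has degree 1. Defaults follow the clusterMaker
implementation of MCODE (degree cutoff 2, node score cutoff 0.2, 2-core,
depth 100, haircut on, fluff off); all are exposed in `mcode_params()`.

## 3. Enrichment

Community enrichment uses the one-sided Fisher test — the hypergeometric
upper tail $P(X \ge k)$, computed exactly — with the network genes as
background, and Benjamini–Hochberg FDR across the whole family of
(community, set) tests of a run, at significance $q < 0.05$. Directionality
is deliberate: enrichment is a one-sided question, and the two-sided default
of `fisher.test` would only dilute power. Sets are intersected with the
background before testing (disjoint sets are skipped with a warning);
communities below `min_community_size = 5` are not tested, matching the
convention of analysing communities with at least 5 genes. GO-style
term-decorrelation algorithms (topGO's weight01) are intentionally out of
scope; classic per-term tests keep the statistical surface transparent. One
caution documented by a test: the BH *adjustment* is not idempotent — only
its rejection set is well-defined — so q-values are thresholded, never
re-adjusted.

## 4. Interaction Strength and super-communities

For disjoint communities $i, j$,

$$IS(i,j) = \frac{\text{observed inter-community edges}}
                 {n_i\, n_j\, \rho}, \qquad
  \rho = \frac{2E}{N(N-1)},$$

the expected count under a global-density (exchangeable-edge) null for the
gene-wise network with $N$ nodes and $E$ edges. The normalisation was an
open design point: the source analysis delegates to an external convention
without reproducing it, so the simplest calibratable null was adopted — on
Erdős–Rényi graphs with arbitrary partitions the mean IS is 1, which the
acceptance suite verifies within 3 standard errors over 100 simulations. A
configuration-model variant ($d_i d_j / 2E$, with $d_i$ the summed degree)
is available via `null = "configuration"`. The community-wise network has
an edge exactly where $IS > 0$; super-community detection re-applies MCODE
to that *unweighted* topology, restricted to communities with at least 5
genes — IS magnitudes rank edges for inspection but do not enter detection.

## 5. Sub-localization

Curated annotations (centrosome database, then GO cilium) take precedence;
a gene in both curated sets is left `unknown`/`unresolved` with a warning
rather than picking an arbitrary winner, since no precedence is defined for
that conflict. All remaining genes are voted: with $A$ = ciliary-group and
$B$ = centrosomal-group experiment counts, the call is ciliary when
$A > B + 1$, centrosomal when $B > A + 1$, and unknown when $|A - B| \le 1$
— a margin requirement that absorbs one experiment's worth of noise. The
test suite checks the implementation against a literal transcription of the
rule on the full $A \in \{0..10\} \times B \in \{0..7\}$ table. The nuclear
flag is independent of the call: nuclear localization co-occurs with either
organelle and is reported alongside, not instead.

## 6. TF target derivation

A TF's candidate targets are the genes whose regulatory window its binding
sites overlap by at least one base. Windows are strand-aware: gene body
plus 10 kb past the 5′ end and 3 kb past the 3′ end (both configurable;
where sources disagree on the downstream extent, the more precise 3 kb
methods value is the default). Coordinates follow the BED convention
(0-based half-open on disk, 1-based in `GRanges`); a mirror-image test
guarantees strand consistency. Candidates are then filtered by
co-expression with the TF: Pearson $r \ge 0.5$ *and* BH $q < 0.05$ from the
one-sided t-test of the correlation, with the BH family being all candidate
pairs of the run. The external co-expression criterion this stands in for
is not published in reusable form, so an explicit effect-size floor plus
FDR was chosen; both knobs are configurable, and raising `r_min` can only
shrink target sets (tested). TFs with no surviving target are dropped.
Target sets then go through the standard community enrichment with
`min_overlap = 5`: a community counts as regulated only when at least five
targets land in it, and TFs are summarised as community-specific versus
shared.

## 7. The synthetic benchmark

`sim_config()` defines the study conditions; its defaults are fixed and are
what the test suite and `scripts/acceptance.R` run:

| parameter | default | emulates |
|---|---|---|
| `n_genes` | 300 | gene universe (a desk-scale stand-in for a few thousand) |
| `community_sizes` | 8, 10, 12, 15 | planted dense modules |
| `p_intra` / `p_inter` | 0.9 / 0.01 | within-block vs background interaction rates |
| `n_channels`, noise sd | 4, 0.05 | evidence channels |
| `n_ciliary_exp` / `n_centrosomal_exp` | 10 / 7 | the two experiment groups |
| `flip_prob` | 0.05 | experiment false positives/negatives |
| `n_terms` | 30 | GO-like collection, one planted term per block |
| `n_tfs` | one per block (≤ 4) | planted regulons |
| `n_conditions`, `expr_noise_sd` | 30, 0.5 | expression panel; target–TF correlation $1/\sqrt{1+sd^2} \approx 0.89$ |
| `p_spurious_site` | 0.02 | in-window decoy sites, so the co-expression filter has something to reject |

Intra-block channel scores are Beta(8, 2) (mean 0.8) with the first channel
bumped when necessary so the pre-noise combined score clears 0.7;
background scores are Beta(2, 8), which places combined scores on both
sides of the cutoff so thresholding is genuinely exercised. Gene models are
10 kb intervals with 30 kb gaps, so 10 kb + 3 kb windows can never overlap
and decoy sites in gap centres are provably outside every window. A single
RNG stream is seeded once in `generate_universe()` and consumed in a fixed
documented order (universe, evidence, experiments, annotations, TF data,
curated sets), so identical configurations give byte-identical files.

What passing the benchmark shows — and does not. It shows the pipeline's
machinery is correct: planted partitions are recovered (mean adjusted Rand
index ≥ 0.9 over 20 seeds at the default conditions), planted enrichments
and regulons are detected, FDR is controlled under the null, and the IS
null is calibrated. It does not show that real interaction databases have
Beta-distributed channel scores, independent channels, disjoint modules or
uncorrelated background pairs — real evidence is heavier-tailed, modules
overlap, and orthology/identifier mapping noise is absent here by design.
Conclusions about any real interactome still require the real inputs.

## 8. Problem sizes and determinism

The shipped tests and the acceptance script run at deliberate desk scale:
a 300-gene universe, exhaustive oracles up to $N = 60$ (Fisher) and 7
vertices (MCODE weights), 20-seed recovery suites and 100–200-replicate
calibration suites; these sizes give stable averages while keeping a full
run in tens of seconds. Everything stochastic flows from explicit seeds
(`sim_config(seed = )`, the `--seed` flag), and pipeline outputs are written
atomically (temp file + rename) so interrupted runs never leave truncated
tables.

## 9. Known limitations

* MCODE is topology-only; combined scores weight nothing downstream of the
  0.7 threshold.
* The global-density IS null ignores degree heterogeneity; the
  configuration-model option mitigates but super-community detection is
  presence/absence either way.
* Classic per-term Fisher tests inherit gene-set redundancy; strongly
  overlapping terms will co-flag.
* The co-expression filter assumes positive regulation (one-sided,
  $r \ge 0.5$); repressive TF–target pairs are invisible to it.
* The localization vote treats all experiments as exchangeable votes; no
  per-experiment reliability weighting.
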