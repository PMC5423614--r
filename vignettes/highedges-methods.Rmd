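---
title: "Mechanism inference from high-scoring interaction edges: models and methods"
author: "highedges package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism inference from high-scoring interaction edges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(highedges)
```

## The problem

A two-phenotype expression comparison (disease vs. healthy, knockout vs.
wild type) is classically summarised by a list of differentially expressed
(DE) genes, selected by arbitrary cutoffs on fold change and p-value. The
resulting gene list is highly sensitive to those cutoffs, and a flat list
says nothing about how the genes act together. `highedges` instead asks
which *known interactions* carry the signal: it scores every gene--gene
interaction recorded in a pathway database by the joint evidence of change
at its two endpoints, chooses the score threshold automatically from the
shape of the score distribution, and reports the connected subnetwork of
high-scoring interactions as the putative mechanism.

## The model

**Per-gene statistics.** For each gene the package computes the log2 fold
change (case mean minus control mean of log-scale normalized intensities)
and a two-sided p-value from a moderated t-test. The moderated test shrinks
each gene's pooled variance $s_g^2$ (on $d_g$ residual degrees of freedom)
toward a prior $(d_0, s_0^2)$ estimated from all genes by the standard
empirical-Bayes method-of-moments fit on log variances; the posterior
variance is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
statistic $t_g = \Delta_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ is referred
to a t distribution on $d_0 + d_g$ degrees of freedom (standard normal when
$d_0 = \infty$; the ordinary pooled t-test when $d_0 = 0$). Genes with zero
pooled variance receive the smallest positive observed variance as a floor
so that constant genes cannot produce infinite statistics.

**Edge scores.** For an interaction between genes $A$ and $B$,

$$\mathrm{EdgeScore}_{AB} = |FC_A| \,(1 - p_A) + |FC_B|\,(1 - p_B),$$

with $FC$ the log2 fold change and $p$ the raw (unadjusted) moderated-t
p-value. Two design choices deserve comment:

* *Absolute fold changes.* Under a signed transform an up- and a
  down-regulated endpoint would cancel, although such an edge (e.g. an
  inhibition) is exactly the kind of interaction one wants to surface. The
  absolute transform is the default; `signed_log2` is available for
  sensitivity analysis.
* *Raw p-values.* FDR-adjusted p-values are compressed toward 1, which
  would flatten the $(1-p)$ weights and blur the separation between signal
  and background edges; the score therefore uses the unadjusted p-value,
  and multiplicity control is applied later, at the pathway-evaluation
  stage, where inference is actually performed.

The score is computed on the *global graph*: the union of all interactions
across all pathways, deduplicated by unordered gene pair (the score is
symmetric in $A$ and $B$, so direction is kept only as display metadata,
and a self-loop would degenerate to $2\,|FC|\,(1-p)$, so self-loops are
excluded). Edges with an unmeasured endpoint are dropped and counted
rather than imputed at $FC = 0$, which would silently halve their scores.

## Automatic threshold selection

The scores of a real comparison form a dense low-score background and a
sparse high-score tail. The critical threshold is found by a single
least-squares change point: with scores sorted in descending order
$s_1 \ge s_2 \ge \dots \ge s_n$, the split index $\tau$ minimises the
two-segment residual sum of squares
$\sum_{i \le \tau} (s_i - \bar s_{1:\tau})^2 + \sum_{i > \tau} (s_i - \bar s_{\tau+1:n})^2$,
and the threshold is the midpoint $(s_\tau + s_{\tau+1})/2$. When the two
regimes are separated the midpoint falls inside the gap between them, which
makes the subsequent edge count insensitive to infinitesimal perturbations
of either population.

We deliberately fit the change point on the sorted scores rather than on
histogram bin counts. A mean-shift split on raw bin counts is dominated by
the smooth high-count background decay: the optimal split slides into the
background and the resulting threshold depends strongly on bin width. On
the sorted scores the same least-squares criterion is bin-free, exact
(computable in one pass from cumulative sums), and deterministic. A
Freedman--Diaconis histogram (with a floor of 30 bins) is still returned in
every `changepoint_result` for diagnostics, since the histogram is the
natural way to *look* at where the distribution becomes flat.

The fit requires at least 20 scores with at least two distinct values;
degenerate inputs are refused with an instruction to use a percentile
cutoff instead.

**Safety margin.** Of the $K$ edges scoring at or above the threshold, only
the top $\lceil 0.75\,K \rceil$ are kept. The change point marks where the
background *begins*; trimming the lowest quarter of the qualifying edges
leaves a margin against borderline false positives. The cut is count-based
and ties at the boundary score are always included, so the selection is a
deterministic prefix of the score-sorted edge list and does not depend on
input order. The fraction is exposed (`safety_fraction`, default 0.75).
Note that for a qualifying set of $K \ge 3$ distinct scores different
fractions in $[0.6, 0.9]$ necessarily select different counts; the
selection is invariant over that whole range exactly when the qualifying
set is tiny ($K \le 2$) or tied — the regime of very small mechanisms,
such as a knockout whose mechanism is a single strong interaction.

**Mechanism extraction.** The mechanism is the subgraph induced by the
selected edges: its gene set is exactly the set of selected-edge endpoints,
partitioned into connected components, with interaction types and source
pathways preserved for rendering (GraphML, SIF and TSV writers are
provided).

## Evaluation harness

Because a knockout (KO) experiment has a known single cause, pathways
containing the KO gene are ground-truth positives. The harness implements:

* **Classical baseline**: genes with $|\log_2 FC| \ge$ `fc_cut` and
  $-\log_{10} p \ge$ `p_cut`, intersected with the universe of genes
  belonging to at least one pathway, plus the subgraph of database
  interactions induced by that list (isolated genes kept as singletons).
* **ORA**: per pathway, the inclusive hypergeometric upper tail
  $P(X \ge \text{overlap})$ for the overlap between the gene list and the
  pathway within the universe, Benjamini--Hochberg adjusted across all
  tested pathways; a pathway is significant at FDR < 0.1. The universe is
  the same for both methods (measured genes in at least one pathway).
* **KO scoring**: TPR = significant positives / positives, FPR =
  significant negatives / negatives, positive likelihood ratio TPR/FPR
  (infinite when FPR = 0 with TPR > 0; reported as 0 when both are 0, and
  infinite ratios sort above all finite ones when picking a best cell).
* **Threshold sweeps**: the classical grid spans $\log_2|FC|$ from 0.5 to
  the observed maximum (step 0.25) and $-\log_{10} p$ from 0.5 to 5 (step
  0.5), least to most stringent; the edge-score sweep spans the change
  point to the maximum score. Grid steps are configurable; per-cell DE
  counts are recorded. An adapter (`read_pathway_pvalues()`) evaluates
  externally computed pathway p-value tables with the same KO scoring, so
  other pathway-ranking methods can be compared without re-implementing
  them.

## The synthetic knockout generator

Real validation data for this problem require a KO experiment and a curated
interaction database; the generator emulates both so the whole pipeline is
testable at desk scale.

**Pathway database.** Ten pathways of 30 genes each. Every pathway graph is
a random recursive spanning tree plus extra random edges up to density
0.11 of the possible pairs (average degree about 3.2, comparable to curated
signaling maps; connectivity is guaranteed by the tree). 18% of each
pathway's genes (after the first pathway) are re-used from earlier
pathways. Two features mirror how curated databases are actually built and
proved essential for the planted mechanism to be recoverable:

* shared genes are drawn as a *connected module* — a degree-weighted walk
  around a seed gene of the accumulated graph — because databases duplicate
  whole signaling cores (receptor--adaptor--kinase chains) across pathways,
  not isolated genes;
* shared genes are wired first in the new pathway's tree, so a re-used gene
  is well connected wherever it appears.

**Planted mechanism.** The KO gene is chosen among genes with global degree
at least 2 whose pathway multiplicity is closest to 3 (the emulated
experiments knock out genes shared by a handful of pathways), tie-broken by
the largest minimum within-pathway degree: knocked-out master regulators
are well wired in every pathway they belong to. The true mechanism is the
breadth-first propagation front to depth 2: every interaction linking a
gene at depth $d-1$ to a gene at depth $d$ carries the knockout signal and
is part of the truth (on paths and stars this reduces to the breadth-first
tree). Expression shifts are inherited through each gene's primary parent
with randomly alternating signs (activation/inhibition): the KO gene
shifts by $-3$ on the log2 scale (a knockdown rather than a hard zero, so
variances stay finite), and a gene at depth $d$ by $-3 \cdot 0.6^d$ in
magnitude.

**Expression.** Controls are $N(\text{baseline}_g, 0.4^2)$ per gene on the
log2 scale (baselines $N(7, 1)$, emulating normalized microarray
intensities, which is also the regime where the moderated-t assumptions
hold); cases add the planted shifts; 5 samples per group; 200 additional
measured genes belong to no pathway and dilute nothing but the measured
gene set. Everything is bit-reproducible for a fixed seed, and
`write_synthetic_inputs()` emits the exact file formats the readers accept
(expression TSV + group table, edge-list TSV, GMT, truth JSON).

**What passing tests do and do not show.** The generator produces clean
Gaussian noise, a single planted cause, perfectly known interactions and
no batch structure, probe-level artifacts, correlated noise or hidden
confounders. Recovery results on it demonstrate the internal consistency
of the method — scoring, thresholding and evaluation behave as designed
when the modelled signal is present — not performance on real microarray
data, where preprocessing, annotation mismatch and database incompleteness
dominate.

## Numerical choices and degenerate inputs

* Change point: exact least-squares fit via cumulative sums; on ties of
  the objective the smallest high segment wins (most conservative
  selection); inputs with < 20 scores or < 2 distinct values are refused.
* Safety margin: `ceiling(round(f * K, 9))` guards against binary
  representation error (e.g. `0.6 * 5` exceeding 3 by 4e-16 must not
  select a fourth edge); boundary ties are included.
* Variance floor: zero pooled variances are replaced by the smallest
  positive observed variance before shrinkage.
* `fit_prior` returns $d_0 = \infty$ when the spread of log variances is
  at or below its sampling floor; the t reference then becomes standard
  normal. (Fully capped degrees of freedom as some implementations apply
  are not used; with homoskedastic data the two conventions differ by
  about $10^{-4}$ in p.)
* ORA with an empty gene list returns $p = 1$ everywhere; an empty
  universe is an error.
* Sweep best-cell ties break toward higher TPR, then more stringent cuts.
* Scored edges are ordered by descending score with lexicographic
  tie-breaks, so count-based cuts are reproducible across platforms.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run the pipeline at the
default generator scale (10 × 30-gene pathways, ≈ 380 unique interactions,
5 vs 5 samples): 50 replicate simulations for planted recovery, 250 for
the null control (whose inclusion-versus-prevalence comparison sits close
to its bound and needs the extra replicates for a stable verdict), 100
seeded runs for change-point separation, and a 10,000-gene simulation for
prior recovery. These sizes make every property statistically decidable
while keeping a full run in the order of a minute.

## Known limitations

* The edge score is direction-blind; an inhibiting interaction whose
  target does not change is invisible to it.
* The change point assumes a *single* transition; multimodal score
  distributions (several distinct mechanisms) are collapsed to one
  threshold. Multiple change points are out of scope.
* On featureless (null) inputs the least-squares split still returns some
  threshold; the method then reports a large, unspecific subnetwork rather
  than declaring failure. Telling "no mechanism" apart from "weak
  mechanism" from the score distribution alone proved unreliable
  (segment-separation and boundary-gap statistics overlap between null and
  planted regimes), so no automatic null guard is applied; users should
  treat a mechanism containing a large fraction of the database as a null
  result.
* Gene identifiers are opaque strings; mapping probe sets or symbols to a
  common namespace is upstream work (a two-column `gene_map` hook is
  provided on graph construction).
* KGML metabolic `reaction` elements are ignored by default (the method
  targets signaling interactions); a flag derives gene--gene edges from
  shared reaction compounds if wanted.
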