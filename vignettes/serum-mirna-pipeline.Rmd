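---
title: "Methods: serum miRNA biomarker discovery and regulatory network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum miRNA biomarker discovery and regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serumiR)
```

`serumiR` implements a biomarker-discovery and network-interpretation
pipeline for case/control serum miRNA studies. This vignette documents the
statistical models, the defaults and why they were chosen, the numerical
conventions, and what the synthetic validation does and does not
demonstrate.

## Differential expression

**Normalisation.** Serum microarray intensities differ between samples by
monotone technical distortions (scanner gain, background, saturation).
Quantile normalisation removes them by forcing every sample onto one common
distribution: the reference is the vector of per-rank row means of the
column-sorted matrix, and each column's values are replaced by the
reference value at their within-column rank. Tied values receive the mean
of the reference over the tied rank span, which keeps the map well defined
and the column multisets identical. The procedure consumes only
within-column ranks, so any strictly increasing per-sample distortion of
the raw data leaves the normalised ranks — and essentially all downstream
calls — unchanged. The one caveat is that the reference distribution itself
is computed from the (possibly distorted) data, so normalised *values* are
not literally identical between a distorted and an undistorted version of
the same experiment; features sitting exactly on a selection threshold can
therefore flip. The test suite checks rank preservation exactly and
confines any call disagreement to those threshold neighbourhoods.

**Testing.** The default test is an empirical-Bayes moderated t on the
(assumed log2-scale) normalised matrix. With per-feature pooled variance
$s^2$ on $d = n_1 + n_2 - 2$ df, the prior $(d_0, s_0^2)$ is estimated by
moment matching on $\log s^2$ (the standard scaled-F fit: the excess
variance of $\log s^2$ over $\psi'(d/2)$ is inverted through the trigamma
function to get $d_0$), and each feature is tested with
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ on $d_0 + d$ df. Degenerate
cases are handled explicitly: if fewer than two features have positive
variance the fit falls back to the ordinary pooled t ($d_0 = 0$); if the
log-variances underdisperse relative to $\psi'(d/2)$ the prior dominates
completely ($d_0 = \infty$, normal reference); features with zero variance
and zero difference get $p = 1$ by convention. A Welch t is available as an
alternative (`method = "welch_t"`). Adjustment is Benjamini–Hochberg via
`p.adjust`; a brute-force evaluation of the step-up definition backs it in
the tests.

**Selection.** DEMs satisfy $|\log_2\mathrm{FC}| \ge 1$ and adjusted
$p < 0.01$ (both configurable); per-cohort lists are sorted by adjusted p
with ties broken by descending $|\log_2\mathrm{FC}|$ and then feature id —
an explicit rule so the top-k truncation (default 500) and the cross-cohort
intersection are deterministic.

## NSR / TFP biomarker scoring

The disease-specific network is the bipartite graph of the DEMs and their
recorded target genes. Two quantities prioritise miRNAs:

* **NSR** — the number of the miRNA's targets with in-degree 1 in this
  network ("single-line regulation"): targets it alone controls.
  Significance is assessed by a permutation null that rewires the bipartite
  edges by checkerboard swaps (two edges $(m_1,g_1), (m_2,g_2)$ become
  $(m_1,g_2), (m_2,g_1)$ when neither replacement exists), preserving every
  miRNA out-degree and gene in-degree; 10 attempted swaps per edge per
  replicate, upper-tail p with the add-one pseudo-count
  $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + B)$ so p is never 0.
* **TFP** — the fraction of the miRNA's targets that are transcription
  factors, tested against the hypergeometric upper tail of drawing its
  `n_targets` from the network's gene universe. The universe defaults to
  the genes present in the disease network (self-contained and
  conservative; a genome-wide universe can be supplied via `universe=`).
  miRNAs with no targets get TFP 0 and p = 1 — they cannot be enriched.

The published tool this scoring emulates does not disclose its analytic
null (its reported p-value magnitudes suggest one); the rewiring and
hypergeometric nulls used here are standard, exactly testable choices that
match the stated intent of the two statistics. Candidates require p < 0.05
on both and are ranked by NSR (ties: ascending p, then id).

## Diagnostics

AUC is computed by the rank formula with half credit for ties, which equals
trapezoidal integration of the empirical ROC curve; orientation is fixed so
AUC ≥ 0.5 and recorded (`direction`). The standard error is Hanley–McNeil
($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$) — a deliberate, documented choice of
CI method since the original tools do not state theirs — and the 95% CI is
clipped to [0, 1]. The Youden-optimal cutoff is searched over midpoints
between adjacent distinct observed values plus $\pm\infty$, which makes J
exact; ties resolve to the lower cutoff.

Panels are fit by binomial logistic regression (IRLS via `glm.fit`,
convergence tolerance `tol`, default 1e-8). Constant members and singular
(collinear) designs are errors; perfect separation is flagged
(`separation = TRUE`) and the finite-iteration coefficients returned rather
than diverging. By default the panel ROC is computed on in-sample fitted
probabilities, mirroring a fit-and-evaluate-per-dataset validation design;
a held-out mode (`newdata`/`newlabels`) is available.

## Network topology and enrichment

Centralities are computed on the undirected simple graph after iteratively
deleting nodes of degree < `min_degree` (default 2) until stable.
Betweenness is unnormalised shortest-path betweenness without endpoint
counting — the common network-tool default; the exact variant used by the
original web tools is unstated, so the convention is recorded here and in
the output. The "similar topology" grouping of miRNAs has no published
algorithm; the package standardises (degree, betweenness) to z-scores and
applies single-linkage clustering cut at merge distance `tau`
(default 0.5 standardised units), a transparent rule whose limits behave
sensibly (`tau` → ∞ gives one group, → 0 gives singletons).
Over-representation analysis is the hypergeometric upper tail against a
user GMT, BH-adjusted across sets, with the universe defaulting to the
genes of the loaded target table.

## MCODE

The module detector follows the original MCODE three-stage design: vertex
weighting by the highest k-core of each vertex's **open** neighbourhood
(weight = core number × core density; implementations differ on
open/closed, so this is stated explicitly), greedy seeded expansion
admitting vertices with weight ≥ seed weight × (1 − node score cutoff)
breadth-limited by `max_depth`, and post-processing that discards
complexes without a `k_core`-core. Note a convention consequence: a vertex
inside an isolated k-clique has weight (k−2)·1, because its open
neighbourhood is a (k−1)-clique whose highest core has core number k−2;
the module score of that clique is still k (density 1 × k members).
Defaults (degree 2, node score 0.2, k-core 2, max depth 100) are the
canonical MCODE defaults; haircut and fluff exist but are off. Modules
selected for miRNA association keep score > `score_min`; the association
count is the number of selected-module member genes a miRNA targets, and
the module-derived miRNA set uses an explicit above-median rule
(configurable), since "strongest association" has no quantitative
published definition.

## Feed-forward loops

The co-regulatory network is restricted to the kept miRNAs, kept genes and
every TF connected to either; miRNA→TF edges are derived from targeting
records whose target is in the TF catalog. Signs default to the standing
biological assumption — miRNAs repress, TFs activate — unless a source
annotates otherwise; duplicate edges merge with the repress annotation
winning (a conservative choice: an experimentally annotated repression
should not be overwritten by a default). Classification is purely
topological; signs are carried for interpretation. Composite loops take
precedence over TF- and miRNA-FFLs so the three classes partition the
qualifying triples; triples with target = TF are excluded as degenerate,
but TFs may occupy the gene role of other triples (dual-role TFs are
reported by `rank_hubs`). Hub rankings are per node kind (TFs and genes
ranked separately, ties by id), with degree = in + out.

## The synthetic-data generator

The generator emulates the study conditions of a serum miRNA microarray
discovery cohort: ~2,500 features, on the order of 100–200 samples per
group (defaults 115 cases / 100 controls), baseline log2 intensities
$\mathcal N(8, 2)$, i.i.d. Gaussian cell noise (sd 0.5), and planted
up-regulated features shifted by 1–3 log2 units in cases (the discovery
design targets up-regulated serum markers with $|\log_2\mathrm{FC}|\ge1$).
The optional per-sample distortion is an affine-plus-cubic map with random
positive coefficients — the simplest strictly increasing distortion that
quantile normalisation must undo. The regulatory generator plants biomarker
miRNAs with an exact number of private single-line targets (default 30)
and a TF share of their total target set (default 0.4, all TF targets in
the shared part so the private count stays exact; every shared target is
additionally covered by one background miRNA so the true NSR is exactly
the private count), plus feed-forward loops wired per class on dedicated
nodes, with background edges re-drawn whenever they would corrupt the
recorded truth (hit a private gene or reclassify a planted loop). The PPI
generator plants disjoint near-cliques (p_within 0.9 by default) in a
sparse background (p 0.01) with uniform confidence scores on [0.4, 1].

What the generator does **not** emulate: probe-level raw intensities,
batch structure, correlated noise between features, miRNA families with
shared seed sequences, database-specific score distributions, or
down-regulated markers. Passing the planted-recovery tests therefore shows
the algorithms are implemented correctly and calibrated under idealised
noise — not that real serum cohorts will yield panels of the same quality.

## Numerical conventions and test design

Deterministic tie-breaks are specified everywhere results could depend on
input order (DEM ordering; MCODE seed order and module sort by score then
seed id; hub ties by id). All generators are exactly reproducible from
their integer seed. Validation problem sizes were chosen to exercise the
stated study conditions while keeping the default test run fast: 100
random networks for the feed-forward-loop oracle comparison, 20 seeds for
planted-recovery experiments (regulatory truth, PPI modules at sizes
15/12/10, logistic coefficient recovery at n = 2000), and 50 pure-noise
simulations at 300 features for false-positive calibration. Module
recovery is assessed in aggregate — the mean best-complex membership
recovery per planted module across seeds — because background bridge edges
occasionally siphon a few members of a smaller planted module into a
larger complex in any single run; this is inherent MCODE behaviour on
bridged near-cliques, not noise in the implementation.

## Limitations

Identifier handling is case-sensitive exact match with no alias resolution
or miRBase version lifting; inputs must use one consistent namespace. All
external regulatory resources are consumed as flat exports — no live
database queries. The permutation NSR p-value has Monte-Carlo resolution
1/(B+1); with the default B = 1000, p-values below ~0.001 are reported at
the floor. Panel evaluation is in-sample by default and will be optimistic
relative to held-out performance; use the held-out mode for honest
validation-set estimates.
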