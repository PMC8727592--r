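---
title: "Reference-based methylation deconvolution: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based methylation deconvolution: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baldecon)
```

## The model

A beta value is the methylated fraction of DNA molecules at a CpG, so for a
sample that is a physical mixture of cell types the observed beta at each
probe is, to first order, the proportion-weighted average of the
constituent cell types' betas. Over a panel of probes chosen to
discriminate cell types this gives the linear model

$$ y \;=\; X w + \varepsilon, $$

with $y$ the mixture's betas over the signature probes, $X$ the
probes-by-cell-types matrix of mean reference betas, and $w$ the cell-type
proportions. The Houseman approach estimates $w$ by least squares under
constraints that make it interpretable as a composition: $w_k \ge 0$,
optionally $\sum_k w_k \le 1$ or $= 1$.

Assumptions worth keeping in view: (i) the reference panel spans the
nucleated cell types actually present — a missing cell type's signal is
absorbed by the most similar reference profile (monocytes, for instance,
load onto alveolar macrophages); (ii) methylation adds linearly in DNA
mass, so cells without DNA (mature red blood cells) are invisible to $y$
and must be handled on the flow-cytometry side, not the methylation side;
(iii) purified-cell profiles are representative of the same cell types
inside mixtures.

## Signature probe selection

For each cell type we compare its reference samples against all other
reference samples, probe by probe, with a classical pooled-variance
two-group test. We report the F statistic (the squared pooled t), its
p-value from $F(1, n-2)$ where $n$ counts non-missing observations at the
probe, and $\Delta\beta$, the in-type minus rest mean. Moderated/shrunken
variants are deliberately not used: with planted or strongly separated
signature probes the classical row test is the transparent choice, and the
hard p-value gate dominates behaviour anyway.

Candidates must pass `p_threshold` (default `1e-8`) *before* ranking — the
threshold defines the candidate pool rather than truncating a ranked list.
Within the pool, mode `"both"` takes the `n_each = 50` most hypermethylated
($\Delta\beta > 0$, ranked descending) and 50 most hypomethylated probes
per cell type; mode `"any"` the `n_any = 100` largest $|\Delta\beta|$.
Whether direction-stratified candidates should be ranked by $\Delta\beta$
or by p within direction is genuinely open; we rank by $\Delta\beta$
(effect size, which is what the projection consumes) and record the choice
in the selection metadata so either convention can be reproduced. Ties
break by larger $|\Delta\beta|$, then smaller p, then probe id, making
selection invariant to input order. The per-type lists may overlap; the
design matrix uses the deduplicated union. Shortfalls are warnings, an
empty candidate set for a cell type is an error.

Degenerate variance is resolved by the limit of the test: zero pooled
variance with differing means gives $F = \infty, p = 0$; identical
constants give $F = 0, p = 1$.

## The projection solver

The constrained least-squares problem is a convex QP in $K$ variables,
where $K$ is the number of cell types — 4 here, rarely above 10 anywhere.
We solve it exactly by **support enumeration**: for every subset $S$ of
cell types, the unconstrained (or sum-to-one, via its KKT system) solution
restricted to $S$ is computed in closed form; candidates violating
non-negativity or the sum constraint are discarded; the feasible candidate
with the smallest residual sum of squares is returned. The optimum of the
QP is the candidate generated by its own support, so the method is exact,
deterministic, and needs no iteration, starting point or step-size — at a
cost of $2^K$ small linear solves per sample, negligible for panel-sized
$K$. Tests cross-check it against an active-set NNLS implementation
(`pracma::lsqnonneg`) and an exhaustive 0.01-resolution simplex grid.

The default configuration is non-negativity only, no sum constraint,
matching the classical estimators: the fitted sum then lands near (not
exactly at) 1 whenever the panel explains the mixture, which is itself a
diagnostic worth preserving. Estimates are reported as raw solver outputs;
any renormalization to exactly 1 is left to the caller as an explicit step.
Missing betas are dropped pairwise per sample — the probe leaves that
sample's projection only — and a sample is rejected if fewer non-missing
probes than cell types remain or the design loses full column rank.
Feasibility of the returned weights is checked at `tolerance = 1e-8`.

## Quality control and normalization

Samples are filtered before probes, so one failed array cannot condemn
probes for everyone. Probe removal takes the union of four causes with
first-cause attribution in the fixed order detection → SNP-at-CpG → sex
chromosome → cross-reactive, making QC reports deterministic. Filters only
remove rows/columns, never alter retained values, and are idempotent.

Normalization is cross-sample quantile normalization (delegated to
`limma::normalizeQuantiles`), optionally stratified by probe design type.
This is a stand-in for the design-aware subset-quantile schemes used on
raw array intensities: those operate upstream of beta values and their
internals are out of scope here. The package normalizes *after* probe
filtering (the order is recorded in the run manifest); since quantile
mapping is monotone within samples, rank-based selection downstream is
insensitive to the order, but exact probe counts from pipelines that
normalized first will not be bit-reproducible.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions under which the pipeline is validated:

* **Background probes** share one mean per probe across cell types, drawn
  from an equal mixture of Beta(0.5, 5) and Beta(5, 0.5) — the bimodal
  (mostly un-/mostly fully methylated) landscape of real arrays.
* **Planted signature probes** give one cell type a mean separated from
  the common mean of the rest by at least `delta` (default 0.5). The rest
  share a single mean so each planted probe discriminates exactly one
  type.
* **Measurement noise** is Beta$(ms, (1-m)s)$ around mean $m$ with
  precision $s$, variance $m(1-m)/(1+s)$ — it respects the $[0,1]$ support,
  unlike Gaussian noise. Means are clipped to $[0.005, 0.995]$ before
  parameterization to avoid degenerate shapes. No published noise level
  exists for sorted-cell replicates, so defaults (precision 500 for
  reference individuals, 200 for mixtures) were fixed once as values giving
  per-probe standard deviations of roughly 0.01–0.03 — typical technical
  replicate scatter for methylation arrays — and are recorded in every run
  manifest rather than treated as tunable.
* **Pooling** of individuals is the per-probe arithmetic mean, because
  equal DNA masses are pooled and beta is a fraction of DNA molecules.
* **Mixtures** draw weights from a Dirichlet (default
  $\alpha = (4, 2, 1, 0.5)$, mirroring the macrophage-dominated,
  AEC-scarce compositions of real BAL) and add beta noise to the
  weight-averaged means. An **unprofiled fraction** per sample (uniform on
  $[0.1, 0.5]$, emulating red-blood-cell contamination) is recorded in the
  truth object, where it dilutes the simulated flow composition, but never
  touches the methylation signal — DNA-free cells contribute none.
* **Detection p-values** are drawn bimodally (pass: $[0, 0.005]$; fail:
  $(0.01, 1]$) so the conventional 0.01 threshold separates them exactly.

What the generator does *not* emulate — probe-chemistry intensity models,
dye and batch effects beyond a label, cell-type substructure such as
alveolar-macrophage subpopulations, spatially correlated CpGs — bounds
what green tests mean: they demonstrate correctness of the algorithms
under the stated generative model, not robustness to every artefact of
real arrays.

## Validation metrics

`scale_flow_proportions` renormalizes a flow composition over the profiled
cell types (×100), the comparison relevant to methylation estimates when
part of the sample is DNA-free; outputs sum to 100 exactly before
rounding. `mse` converts both tables to the fraction scale before
averaging squared differences, so reported MSEs are on the fraction² scale
regardless of input units; the per-subject reading (mean over cell types
within a subject) is the one consistent with a subject-level discrepancy
of ~0.06 for the bundled CF1 data, and both axes are available.
Bland–Altman uses difference = estimate − truth against the pair mean,
with limits bias ± 1.96·SD. The invariant-probe check finds probes ≥ 0.95
(or ≤ 0.05) in *every* reference cell type and reports the fraction
staying on the same side of 0.5 in each mixture — a foreign *nucleated*
cell type pulls them toward the middle, a DNA-free one cannot. The
pooling-variance regression is ordinary least squares of per-sample
variance (across all retained probes, not just signature probes — the
question is global representativeness) on pool size. The MDS diagnostic is
classical scaling (`stats::cmdscale`) of Euclidean distances over the most
variable probes.

## Problem sizes and determinism

The bundled tests and the acceptance script run on panels of 200–5,000
probes, 3 reference individuals per cell type and 5–20 mixtures — sizes at
which every statistical check (noiseless recovery to 1e-6, per-cell-type
recovery MSE below 0.005 at noise precision 200, type-I error of the
one-vs-rest test, grid-search agreement of the solver) is already stable;
full-array scale (~850k probes) adds nothing but time to these checks.
All randomness flows through explicit integer seeds; identical seeds give
bit-identical outputs, including the CSVs written by `run_end_to_end`.

## Known limitations

* Cell types absent from the reference panel bias estimates toward their
  nearest profiled neighbour; the row-sum diagnostic flags gross cases
  but cannot localize them.
* The quantile-normalization stand-in is not the intensity-level
  design-aware scheme; probe-level counts from such pipelines will differ.
* The equal-variance F test assumes exchangeable reference samples within
  a cell type; pooled samples with very different pool sizes mildly
  violate this (the pooling-variance regression is the check).
* Proportions are estimated per sample independently; no information is
  shared across samples, and uncertainty intervals for $\hat w$ are not
  provided.
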