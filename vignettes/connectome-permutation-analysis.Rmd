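---
title: "Methods: permutation inference for parcellated functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation inference for parcellated functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoperm)
```

## Overview

`connectoperm` implements a complete group-analysis pipeline for
parcel-level resting-state functional connectomes. The input is one BOLD
time-series matrix per subject (timepoints x parcels, already
preprocessed and averaged within parcels), an atlas table assigning each
parcel to one of the seven canonical Yeo cortical systems (VN, SMN, DAN,
VAN, LN, FPN, DMN), and a phenotype table with a two-level group factor,
four nuisance covariates (age, sex, mean framewise displacement, cortex
volume) and clinical scores. The pipeline then proceeds through five
inferential stages:

1. **Connectivity**: per-subject Fisher-z matrices of Tikhonov (ridge)
   regularized partial correlations.
2. **Graph metrics**: binary graphs across a proportional-density grid;
   eight global and three nodal metrics, each summarized by its area
   under the curve (AUC) over the grid.
3. **Group inference**: covariate-adjusted permutation tests with
   max-statistic family-wise correction and Benjamini-Hochberg FDR.
4. **Network-Based Statistic (NBS)**: supra-threshold connected
   components of edge-wise effects, tested against a permutation null of
   maximum component size.
5. **Block connectivity and clinical correlation**: Yeo-network
   within/between block averages, and covariate-controlled Pearson
   correlations between network indices and clinical scores in patients.

A seeded synthetic cohort generator provides ground truth for every
stage, so the pipeline's operating characteristics (family-wise error,
power, null behaviour of the clinical scan) are themselves testable.

## Connectivity model

Each subject's columns are standardized, the sample correlation matrix
$R$ is formed, and the ridge precision
$\Theta = (R + \lambda I)^{-1}$
is inverted to partial correlations through the standard map
$p_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}$,
followed by the Fisher transform $z = \operatorname{artanh}(p)$.

Choices that matter:

* **Ridge on the correlation (not covariance) matrix.** This makes the
  estimator invariant to affine rescaling of any input channel and
  always well-posed, including when the number of timepoints is below
  the number of parcels (T = 170 vs N = 400 in the design the package
  targets). The published description of the estimator this mirrors
  does not state its formula or penalty; regularizing the correlation
  matrix is the scale-free reading and is documented here as the main
  reproducibility gap.
* **Default `lambda = 1`.** With T < N some positive penalty is
  mandatory; 1.0 shrinks strongly but preserves the ranking of
  conditional associations, and every result in the package is reported
  with the penalty recorded in the run metadata. There is no automatic
  penalty tuning: a fixed value keeps results deterministic, and tuning
  hooks can be layered on later without changing any interface.
* **Clipping at |r| = 1 - 1e-7** before `artanh`, so that degenerate
  inputs (duplicated or antithetic channels under the plain-Pearson
  option) produce large finite z-values instead of infinities, which
  downstream proportional thresholding handles without special cases.

As `lambda -> 0` on well-conditioned data the estimator converges to the
exact partial correlation, and as `lambda -> inf` all off-diagonal
entries shrink monotonically to zero; both limits are enforced by tests.

## Binary graphs and metrics

Graphs are built by **proportional thresholding**: at density $s$ the
$k = \operatorname{round}(s \cdot N(N-1)/2)$ edges with the largest
*signed* z survive. The default grid is 10% to 34% in 1% steps
(25 densities), stored as exact hundredths so that repeated analyses
never drift across float representations. Ties (exactly equal z) are
broken by ascending lexicographic edge index, making every graph a
deterministic function of its matrix; `round()` follows R's
round-half-even rule. Thresholding on signed rather than absolute z
follows the binary-graph convention of keeping the strongest positive
couplings; with ridge-shrunken partial correlations, large-magnitude
negative edges are rare, but the choice is recorded here because either
convention changes exact metric values without changing any contract.

Global metrics per density: mean clustering coefficient $C_P$ (local
value defined as 0 for degree < 2, the Watts-Strogatz convention),
characteristic path length $L_P$, global efficiency $E_{glob}$, local
efficiency $E_{loc}$, degree assortativity, and the normalized
$\gamma = C_P / C_P^{rand}$, $\lambda = L_P / L_P^{rand}$ and
small-worldness $\sigma = \gamma/\lambda$. Nodal metrics: degree, exact
(Brandes) unnormalized betweenness, and nodal efficiency
$\frac{1}{N-1}\sum_{j \ne i} 1/d(i,j)$.

Numerical conventions worth stating explicitly:

* **$L_P$ on disconnected graphs** is the mean shortest path over pairs
  inside the largest connected component. At 10% density a 400-node
  graph is frequently disconnected; restricting to the giant component
  keeps $L_P$'s classical meaning while $E_{glob}$ (where unreachable
  pairs contribute 0) carries the disconnection signal.
* **$E_{loc}$** is the mean over nodes of the global efficiency of the
  subgraph *induced by the node's neighbours*. Another convention in
  circulation computes neighbour-pair distances in the whole
  vertex-deleted graph and yields systematically larger values; the
  induced-subgraph form used here is the one the brute-force oracle in
  the test suite implements.
* **Assortativity** is the Pearson correlation of degrees over edge
  endpoints and is undefined (NaN) on degree-regular graphs; such
  outcomes are dropped pairwise from their permutation family with a
  warning rather than silently imputed.
* **Random-graph normalization** uses Maslov-Sneppen double-edge swaps:
  10|E| *successful* swaps per null graph (attempted swaps that would
  create self-loops or multi-edges are rejected and retried, with a
  bounded retry budget so that unswappable graphs such as complete
  graphs come back unchanged, correctly giving gamma = lambda = 1).
  The default is 100 nulls per subject and density; the simulations in
  the test-suite use 2, which is enough for the permutation tests'
  validity since gamma/lambda enter them only as (noisier) outcome
  variables.
* **AUC** is the trapezoidal integral of the metric against density, the
  parameter-free summary used instead of per-density inference. The
  "sum times step" convention of some toolboxes is available as an
  option (`method = "step_sum"`); on the uniform default grid the two
  differ by a boundary term only.

The metric core is implemented in compiled code (BFS distances, triangle
enumeration, Brandes betweenness, in-place rewiring) and is verified in
the test suite along two independent routes: against igraph on the
metrics where conventions coincide, and against deliberately naive
brute-force oracles (Floyd-Warshall distances, adjacency-power
shortest-path counting, exhaustive triangle enumeration) on hundreds of
random graphs, to 1e-12.

## Permutation inference

All group contrasts share one engine. The design matrix is
[intercept, group, age, sex, meanFD, cortex volume] with group
(patient = 1) as the tested contrast. Permutation follows the
**Freedman-Lane** scheme: outcomes are residualized on the nuisance
columns, residual rows are permuted, the nuisance fit is added back, and
the full model is refit — preserving the covariate structure under the
null. With no covariates this reduces exactly to group-label
permutation (a tested identity). P-values use the add-one convention
$p = (1 + \#\{|t^{null}| \ge |t^{obs}|\})/(B+1)$, which cannot return
zero and makes the test exact up to permutation discreteness.

Family-wise correction records, per permutation, the **maximum |t| over
the family**, and compares each observed |t| to that null. The families
mirror the reporting granularity of density-integrated connectome
studies: the 8 global AUC metrics form one family; each nodal metric's
N parcels form their own family; the 28 block values form one family
(tested by uncorrected permutation p followed by BH-FDR, matching how
block analyses are conventionally corrected). FDR is Benjamini-Hochberg
throughout (`stats::p.adjust`). AUC values, not per-density values, are
tested — the grid exists to remove threshold dependence, and testing
every density would reintroduce it.

The **NBS** applies the same engine edge-wise: one GLM per
upper-triangular edge, a primary two-tailed threshold (default
p < 0.001) on the *parametric* t-distribution p-value, connected
components of surviving edges per direction, and a Freedman-Lane
permutation null of the maximum component size (edge count). Each
direction (patients > controls, patients < controls) is its own
one-tailed family at alpha = 0.025. The primary threshold is parametric
because an edge-level permutation p of 0.001 would itself require
thousands of permutations per edge; the permutation enters where NBS
needs it, at the component level. Component "size" is extent (edge
count); the corrected p uses >= with add-one smoothing, so a component
larger than every null maximum gets p = 1/(B+1), never 0. Reporting
merges both directions into a single edge table plus a per-direction
component list and a Yeo network-pair tally (hypo/hyper counts and the
ratio to each pair's total possible connections).

The **clinical scan** correlates patient network indices with clinical
scores as the Pearson correlation of OLS residuals after projecting out
the covariates, with parametric two-tailed p on
$df = n - 2 - n_{cov}$ and BH-FDR across the scan. Parametric rather
than permutation p is used here because this stage is a plain
correlation screen, not a max-statistic family. By default the scanned
indices are the 8 global AUC metrics (AUC, not per-density values, for
the same reason as above); any table of indices can be supplied.

## The synthetic cohort generator

The generator is a first-class module, not a test fixture. It emulates
the study design the pipeline targets:

* two groups of 35 patients and 40 controls, 170 retained timepoints at
  TR = 2 s;
* Gaussian parcel series with **block-structured spatial correlation**
  keyed to the atlas labels: within-network correlation 0.4,
  between-network 0.1 by default;
* **AR(1) temporal autocorrelation** (phi = 0.3 by default) as the
  simplest stand-in for band-passed BOLD — it reproduces the inflated
  variance of covariance estimates that band-passing causes, which is
  what matters for the downstream statistics; phi = 0 reproduces
  i.i.d. sampling exactly on the same RNG path;
* covariates drawn group-matched (age ~47/45 years, sex ratios ~6:29 and
  ~13:27, log-normal mean FD around 0.05 mm, cortex volume around
  4.9e5 mm^3), anxiety/depression scores that differ by group, and a
  constipation score defined for patients only — the shape of a matched
  case-control sample in this literature;
* injectable group effects on single edges or whole network blocks,
  applied to the patient group's target correlation matrix, clipped to
  |r| <= 0.95 and repaired to positive definiteness by eigenvalue
  clipping at 1e-6 (deterministic, flagged in the truth record) when an
  injection breaks it.

What the generator does **not** emulate: hemodynamic response shapes,
head-motion artifacts and their correlation with group, spatial
autocorrelation along the cortical surface, scanner/site effects,
non-Gaussian tails. Passing operating-characteristic tests on this
generator therefore demonstrates that the *inference machinery* is
correct (error control, recovery, alignment, determinism) — not that
any particular real-data finding is reproducible, which would require
the original scans.

## Problem sizes used by the test suite

The statistical acceptance checks run at a deliberately reduced scale
chosen to exercise every code path with meaningful Monte-Carlo
precision: 40-parcel atlases, cohorts of 20+20 (error control) or 35+40
(recovery), 1,000 permutations, 2 rewired nulls per density, 200 null
cohorts for family-wise error, 100/50/30 replicate runs for the
block, sub-network and global-metric recovery rates, and 100 replicate
clinical scans. `scripts/acceptance.R` recomputes the same quantities at
comparable sizes. The defaults of the package itself remain the
full-scale settings (400 parcels, 10,000 permutations, 100 nulls).

## Known limitations

* The ridge penalty of the toolbox the connectivity estimator mirrors is
  unpublished; results depend on `lambda`, and cross-study comparisons
  should fix it explicitly.
* Whether thresholding should use signed or absolute z is a convention
  choice; the package uses signed z and records it.
* Weighted-graph metrics, modularity/hub analyses, TFCE-style cluster
  statistics and exchangeability blocks are out of scope.
* The NBS reports per-direction components plus a merged union summary;
  studies that merge directions before component formation would count
  differently.
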