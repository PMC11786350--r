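---
title: "Graph-regularized NMF deconvolution: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-regularized NMF deconvolution: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastdeconv)
```

## The deconvolution problem

A capture spot in sequencing-based spatial transcriptomics covers tens of
cells, so its expression vector is a mixture of cell-type profiles.
`fastdeconv` estimates, without any single-cell reference, both the per-type
gene signatures **W** (N genes × R types) and the per-spot abundances **H**
(M spots × R types) by minimizing

$$\lVert X - WH^\top\rVert_F^2
  + \lambda_1\,\mathrm{Tr}(H^\top L H)
  + \lambda_2\,\lVert HJ - J_M\rVert_F^2,
  \qquad W \ge 0,\; H \ge 0 .$$

The three terms trade off reconstruction of the data, spatial/histological
smoothness of the proportions, and a sum-to-one scale on each spot's
proportions. The sum-to-one penalty is evaluated through the identity
$\lVert HJ - J_M\rVert_F^2 = M\sum_j(\sum_r H_{jr}-1)^2$, so the all-ones
matrices are never materialized; `fast_objective()` and a test against the
explicit-matrix form keep this identity honest.

### Assumptions

* Expression mixes additively: a spot is (approximately) the sum of its
  cells' transcripts, so a low-rank non-negative factorization is the right
  generative shape.
* Spots that are close on the array *and* look similar in the histology
  image tend to share cell-type composition. Where tissue is organized in
  thin or curved structures, physical distance alone misleads; the fused
  distance lets stain intensity discriminate.
* The number of cell types R is modest and smaller than both N and M.

## The spot graph

`build_spot_graph()` turns coordinates (plus optional intensity) into the
Laplacian the solver consumes:

1. **Intensity.** `spot_intensity()` takes the median grey value of a
   `window × window` (default 5×5) pixel square around each spot center,
   clipped at image borders. Medians resist stain speckle. `max_intensity`
   (default 1) rescales integer images; PNG input read by `png::readPNG()`
   is already in [0, 1]. A lattice-style alternative — medians over
   neighboring *spots* rather than pixels — can be emulated by passing
   spot-level intensities directly as `z`.
2. **Fusion weight.** `compute_beta()` uses the squared coordinate ranges
   over the squared intensity range, which puts one full intensity swing on
   the same footing as the array diameter. A flat or missing image yields
   `beta = 0` (the histology term vanishes) rather than an error — the
   natural limit for an uninformative stain.
3. **Sparsification.** Each spot keeps its `k = 5` nearest neighbors under
   the fused squared distance. Distances are converted to similarities
   *before* any "largest entries" are kept, so retention selects near spots
   — the standard graph-regularized NMF construction, and the only reading
   under which the trace term penalizes disagreement between neighbors.
   Binary weights are the default; a heat-kernel mode
   (`exp(-d²/σ²)`, σ² = median kept squared distance) is available when
   graded affinity matters. Row selections are symmetrized by elementwise
   maximum (guaranteeing a symmetric PSD Laplacian); a mutual-kNN flag
   gives the stricter intersection graph. Ties in the distance ranking
   break toward the lower spot index, for determinism.

Every constructed graph satisfies `L·1 = 0` and
$\mathrm{Tr}(H^\top LH) = \tfrac12\sum_{jl}G_{jl}\lVert h_j-h_l\rVert^2 \ge 0$;
both are enforced by tests against loop-based oracles. Note one property a
kNN union graph does *not* have: a popular spot may be chosen by more than
`k` neighbors, so individual row degrees can exceed `2k`; only the mean row
degree is bounded by `2k`.

## The solver

`fast_fit()` alternates two multiplicative updates, derived by the standard
KKT/auxiliary-function route with `L` split into `D − G` so numerator and
denominator are separately non-negative:

* `W ← W ⊙ (XH) ⊘ (W HᵀH + ε)`
* `H ← H ⊙ (XᵀW + λ₁GH + λ₂M𝟙) ⊘ (H WᵀW + λ₁DH + λ₂M H𝟙 + ε)`

Correctness is pinned by properties rather than formulas copied from
anywhere: the objective is non-increasing across every tested
`(λ₁, λ₂) ∈ {0, 0.01, 1, 10}²`; with both penalties off the iterates match
an independently coded plain multiplicative NMF to 1e-10; and at
convergence the complementarity residual `min(H, |∂f/∂H|)` vanishes on
planted instances.

### Tunable parameters

| parameter | default | meaning and guidance |
|---|---|---|
| `R` | — | number of cell types; see rank selection below |
| `lambda1` | 1 | graph smoothing. Near 0.01 the fit behaves like standard NMF; above ~10 the solution follows the graph more than the data. 1 balances the two, and is the default used throughout |
| `lambda2` | 1 | sum-to-one pressure; raising it tightens `rowSums(H)` toward 1 monotonically (tested over 0–100) |
| `k` | 5 | neighbors per spot in the graph |
| `beta` | auto | histology weight (range-ratio rule); 0 disables histology |
| `max_iter`, `tol` | 1000, 1e-5 | stop when the relative objective change drops below `tol`; multiplicative updates converge slowly near the optimum, so raise `max_iter` for publication-grade runs |
| `eps` | 1e-12 | denominator floor; prevents 0/0 without perturbing converged values |
| `init` | random | uniform(0,1), seeded. `"nndsvd"` (non-negative double SVD, zeros replaced by `mean(X)/100`) starts lower but less diversely — use random restarts for stability scans |

No internal normalization is applied to X: counts and pre-normalized values
are both accepted, and what you put in determines the scale of W. Reported
proportions are the row-normalized H (`spot_proportions()`), since the
penalty only *encourages* unit sums; the raw H remains in the fit object.
An all-zero H row normalizes to the uniform vector with a warning.

## Rank selection

The number of cell types is the critical hyperparameter and cannot be read
off the data directly. `scan_ranks()` fits each candidate R with several
seeded restarts and reports reconstruction error, explained variance, and a
restart-stability score (mean absolute correlation of greedily matched W
columns across restart pairs). `suggest_rank()` applies an elbow criterion:
the interior candidate farthest (perpendicularly, after normalizing both
axes) from the chord joining the first and last points of the error curve,
ties toward the smaller rank. These are this package's own criteria —
pragmatic, deterministic and testable — not an attempt to reproduce any
particular published selection recipe; on planted factorizations the elbow
recovers the true rank.

## What the simulator emulates — and what it does not

`simulate_study()` reproduces the structure of a layered-tissue benchmark:

* **Regions.** `mob_table1_design()` encodes three concentric layers with
  75 (granule), 140 (mitral) and 45 (nerve) spots and per-region Dirichlet
  parameters (1,3), (3,1), (1,1) over two cell types — 260 spots. Spots are
  placed uniformly in equal-width annuli (granule innermost), and each
  region gets a distinct synthetic grey intensity (0.35/0.60/0.85, SD 0.03)
  so the histology term is exercisable.
* **Spots.** Each spot draws proportions from its region's Dirichlet,
  assigns `cells_per_spot = 10` cells multinomially, and sums NB-distributed
  per-cell counts (dispersion 0.5; a sum of n i.i.d. NB(μ, size) cells is
  drawn exactly as NB(nμ, n·size)). The *realized* cell fractions are the
  ground truth H, so truth rows sum to one exactly.
* **Genes.** Signatures are synthetic: log-normal baseline means with
  disjoint marker blocks (20% of 500 genes, 4-fold elevation). A synthetic
  single-cell pool (100 cells/type) is filtered by a Wilcoxon rank-sum test
  per gene with Benjamini–Hochberg adjustment at p < 1e-5 before spots are
  assembled, mirroring marker preselection on a reference atlas. The
  rank-sum (Mann–Whitney) test is used because the groups are independent
  cells; the vectorized normal-approximation implementation is checked
  against `stats::wilcox.test` in the tests.

What it does **not** emulate: real single-cell pools (sparser, with
library-size variation, ambient RNA and correlated programs), real
histology (texture, artifacts, registration error), platform-specific
spot geometry, or more than a handful of cell types by default.
Passing tests on this generator show the estimator recovers compositions
under its own generative assumptions with clean markers; they do not bound
performance on real slides, where marker separation and graph fidelity are
both worse. The defaults above were chosen once as a realistic-but-clean
operating point and are not tuned per analysis; sample sizes in the test
suite (e.g. 40×30 random instances, 10 simulation replicates) are the
package's chosen verification scale.

## Numerical choices and edge cases

* Ties: distance ranking and factor-annotation argmax both break toward the
  lower index; variable-gene ranking breaks by gene order.
* Degenerate inputs: constant `z` → `beta = 0`; zero-variance signature
  columns get correlation −∞ in annotation (warning); constant proportion
  columns score correlation 0 (warning) so the mean stays defined;
  all-zero count rows/columns are dropped at read time with a message.
* Evaluation conventions: factors map many-to-one onto reference types by
  maximum signature correlation; co-assigned factors' proportions are
  *summed* before scoring and unmatched reference types score 0 — a
  conservative, total rule. RMSE compares row-normalized proportions.
  The mean Pearson weights types equally, not by abundance.
* Determinism: every stochastic step (init, simulation, K-means) takes a
  seed; identical seed + config + input give bit-identical output.

## Known limitations

* Multiplicative updates stall near zero entries; KKT-level convergence can
  need tens of thousands of sweeps on ill-conditioned instances.
* The factorization is unique only up to scale/permutation even with the
  sum-to-one penalty; interpret factors through their signatures.
* One slide at a time; no KL-divergence objective; no learned texture
  features for the adjacency — the grey-median is deliberately simple.
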