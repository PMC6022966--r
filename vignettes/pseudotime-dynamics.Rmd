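---
title: "Pseudotime dynamics of expression signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudotime dynamics of expression signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptdyn)
```

## The problem

Single-cell RNA-seq of a tumour culture captures a snapshot of cells spread
along an unobserved axis of progression. Under the pseudotime assumption —
cells at many stages coexist, and transcriptional state changes smoothly in
small increments — an ordering of the cells by transcriptome similarity can
stand in for that axis. `ptdyn` implements a linear (non-branching)
pseudotime pipeline for small, deeply sequenced cultures (tens to a few
hundred cells, FPKM-like quantification), and the downstream machinery to
ask *which* cellular programs move along it and *how* programs move relative
to one another. The motivating system is melanoma short-term cultures, whose
canonical programs (stromal, proliferation, oxidative phosphorylation,
glycolysis, the antagonistic MITF/AXL axis, poised and active promoter
activity) name the package's defaults, but nothing in the machinery is
melanoma-specific.

## Pipeline and model

1. **Preprocessing.** Cells expressing *neither* of two housekeeping genes
   (ACTB, GAPDH; FPKM > 0 is "expressed" — zero is the only unambiguous
   "not expressed" on that scale) are removed as failed libraries. Quantile
   normalization then forces an identical value distribution on every cell.
   We make "identical" exact: every column becomes a permutation of the
   common reference (the across-cell mean of sorted columns). A group of
   tied values — overwhelmingly dropout zeros — collectively receives the
   reference values of its rank span, rather than their mean: assigning tie
   means would leave cells with different numbers of zeros with measurably
   different distributions, defeating the purpose of the step. An externally
   cell-cycle-corrected matrix can be substituted at this point
   (`preprocess_matrix(..., filter = FALSE)`); no cell-cycle correction is
   performed in-package.

2. **Gene-level scores.** Per-gene z-scores of `log2(FPKM + 1)` across
   cells. Zero-variance genes carry no ordering information and are dropped
   with a warning.

3. **Gene set Z-score (GSZ).** For a set of `m` genes among `N`, per cell:
   `GSZ = (S - m * mu) / sqrt(m * sigma^2 * (N - m)/(N - 1) + lambda)`, with
   `S` the set sum, `mu` and `sigma^2` the mean and population variance of
   all gene scores in that cell. This is the exact mean and variance of the
   sum of `m` scores drawn without replacement from the cell's gene scores,
   so GSZ is the z-score of the set against random same-size sets — the
   package's tests pin this against an explicit permutation oracle. The
   additive regularizer `lambda` (default 0) guards degenerate cases such as
   a set covering the whole matrix. Because gene scores are standardized,
   the GSZ null is calibrated near mean 0, variance 1.

4. **Pseudotime.** An ensemble of k-nearest-neighbour graphs over cells:
   distances are correlation distances (`1 - Pearson r`) between
   standardized full transcriptomes (configurable to euclidean); each of
   `n_graphs = 20` members keeps a seeded uniform subsample of `l = 8` of
   each cell's `k = 16` neighbours and symmetrizes. `k = 16` follows the
   study design this pipeline reproduces; orderings are empirically stable
   for `k` in 10–20. A disconnected member is repaired deterministically by
   repeatedly adding the globally shortest edge between two components —
   with 54–84 cells and subsampling, occasional fragmentation is expected
   and must not abort a run. Per member, each cell's trajectory is its
   weighted shortest-path distance from the start cell; pseudotime is the
   per-cell mean over members, affinely rescaled to [0, 1]. The start cell
   maximizes the stromal GSZ (ties break to the lexicographically smallest
   cell id); if the top pseudotime decile has lower mean proliferative GSZ
   than the bottom decile, the axis is reversed. Pseudotime has no temporal
   unit. Waypoint refinement from the original ensemble-graph algorithm is
   deliberately omitted: the implemented definition is exactly
   "mean of shortest-path distances".

5. **Slow-component breakpoint.** Pseudotime (y) against normalized cell
   rank (x) is fit with one line and with a continuous two-segment line
   whose knot is scanned over interior ranks (≥ 5 cells per side). If the
   two-segment fit reduces the residual sum of squares by at least 25%
   (relative), the fitted pseudotime at the knot is reported as the
   characteristic value where the flat initial component hands over to the
   fast one. An exactly linear curve fits with essentially zero residual;
   improvements are defined as 0 whenever the one-line residual is below
   `1e-10` of the total sum of squares, so a perfect line never reports a
   breakpoint.

6. **Profiles.** LOESS (tri-cube local polynomial, exact `surface =
   "direct"` computation, hence deterministic) smooths PT-ranked GSZ values;
   span 0.5. The default degree is 1: on 50–100 unevenly spaced points,
   local-quadratic fits systematically overshoot at the boundaries, which
   pushes the smooth's extremes to the edges and corrupts the relative
   activity defined next; local-linear fits do not, and reproduce linear
   signals exactly. Degree 2 remains available. Relative activity rescales
   each smooth affinely to min 0 / max 1 (an error for constant smooths —
   no silent division by zero). Biaxial trajectories pair two smoothed
   curves point-wise along pseudotime; this is the "two univariate fits
   against PT" construction, not a 2-D smoother.

7. **Pseudotime association.** For each gene or set: a Gaussian linear
   model on a natural cubic spline basis of pseudotime (`spline_df = 3`
   plus intercept) against the intercept-only model;
   `LR = 2 * (loglik_full - loglik_reduced) = n * log(RSS0/RSS1)`; p from a
   chi-square with `spline_df` degrees of freedom; Benjamini–Hochberg FDR
   across the run; direction from the sign of the Spearman correlation with
   pseudotime (ties count as correlated — the spline itself is sign-blind).
   Fixed-df natural splines give a well-defined chi-square reference; no
   penalized smoothness selection is attempted. The chi-square reference is
   asymptotic: at n = 80 the exact null rejection rate at nominal 0.05
   works out to about 0.058 (the statistic is a monotone function of an F
   statistic, so this can be computed exactly), which the calibration test
   accommodates within its binomial 99% band.

8. **Trajectory typology.** Five qualitative modes of pairwise program
   geometry are made operational with committed, configurable thresholds
   (`typology_control()`). On curves rescaled to the unit square:
   *switch-like* — one axis completes 80% of its range before the other
   completes 20% (strict rule), or both axes travel the same net direction
   with half-range crossing times separated by ≥ 15% of the pseudotime
   range (relaxed rule, capturing "plateau then hand-over" under noise);
   strongly anti-correlated pairs are excluded — sequential same-direction
   activation and anti-correlation are mutually exclusive.
   *parallel anti-correlated* — Pearson r ≤ −0.8 between the two smooths,
   evaluated on the curve's own support (observed cells); at that
   correlation the point cloud is already confined to an aspect ratio of
   about 1/3 around a falling line, so no separate straightness test is
   needed. *divergent* — only meaningful across branches (separate
   cultures): strongly anti-correlated axes whose branch terminal states
   (mean of the last pseudotime decile) separate by ≥ 0.4 on each axis in
   opposite directions. Within a single branch divergence is not
   identifiable and collapses to parallel anti-correlated. For multi-branch
   input the divergent check runs before the parallel rule, since each
   branch of a divergent pair is itself a straight anti-diagonal.
   *orthogonal* — |r| ≤ 0.3 with one axis confined to a band of ≤ 0.3
   while the other is active. *curved* — a bow (maximum perpendicular
   deviation from the endpoint chord, normalized by chord length) above
   0.45 when no earlier rule fired. The classical path-based curvature
   index `1 - chord/path` is reported alongside but is not decisive: it
   counts backtracking along the chord as curvature, which makes it
   unstable on smoothed noisy anti-diagonals. Axis-swap leaves labels
   unchanged (the leading axis of a switch is reported and swaps).

Each culture is processed independently end to end; `run_pipeline()` wires
the stages together, echoes every parameter into a provenance JSON, logs
per-stage wall time, and is byte-reproducible given a configuration and
seed.

## The synthetic-data generator

`simulate_expression()` draws a latent pseudotime `t ~ Uniform(0, 1)` per
cell and builds gene modules whose mean log2 expression follows fixed
temporal shapes: a decreasing sigmoid (stromal collapse), a delayed ramp
(cell cycle), a saturating exponential (oxphos), a late-rising ramp
(glycolysis), a rising logistic and its complement (the bipolar MITF/AXL
pair), and linear up/down references (active/poised promoter activity).
Expression is `baseline + amplitude * f(t) + Normal(0, noise_sd)` in log2
units, mapped to an FPKM-like scale by `2^x - 1` truncated at zero, with
Bernoulli dropout and two always-on housekeeping genes that are zeroed in a
configurable fraction of "failed" cells.

Defaults define the reference conditions used throughout the tests: module
sizes 25–40 genes, amplitudes 2–3 log2 units (4–8 fold dynamic range, the
scale of strong transcriptional programs), 100 background genes,
`noise_sd = 0.5` log2 units, `dropout_rate = 0.1`, baseline log2 expression
3 (housekeeping 8, far from dropout ambiguity). The three-culture fixture
(`paper_like_fixture()`) mirrors the 84/54/77-cell culture sizes, with the
third culture carrying the swapped MITF/AXL polarity (AXL-high late), so
the cross-culture divergent geometry is representable. No quantitative
noise or dropout characteristics were available for the real cultures;
these values were chosen once for realism and testability and are not
tuned.

What the generator emulates — and what it does not: it produces latent-
trajectory-driven module structure, log-normal noise, dropout and failed
cells, but no batch effects, doublets, branching lineages, gene–gene
correlation beyond module membership, or sequencing-depth variation (FPKM
is assumed already depth- and length-normalized). Passing the synthetic
acceptance surface therefore demonstrates the *algorithms* recover known
structure under these noise modes; it does not certify performance on real
data with artefacts the generator omits.

## Numerical choices and degenerate inputs

* **Metric degeneracy.** With a *single* informative module and no noise,
  every non-constant gene is the same function of `t`, so each cell's
  profile across genes is constant and correlation distance is undefined
  (and under noise it sorts cells by activation magnitude, folding the
  trajectory). Exact-recovery checks on that fixture therefore use the
  euclidean metric; the multi-module default uses correlation distance,
  which is robust to per-cell scale. `l = k` gives a deterministic,
  degenerate ensemble (all members identical), used where exactness rather
  than ensemble averaging is under test.
* **Zero distances** between duplicated profiles are lifted to a tiny
  positive floor so edge weights stay strictly positive.
* **Neighbour ties** break by cell index; start-cell ties break by cell id;
  both make runs reproducible without a seed dependence.
* **Constant responses** in the association test return `LR = 0, p = 1` by
  definition rather than erroring.
* Problem sizes in the tests and acceptance script (84–100 cells, 200–350
  genes, 10–50 replicate refits, 2,000 null replicates, 100,000 permutation
  draws) were chosen so the full suite exercises every claim at meaningful
  precision while remaining a desk-scale run.

## Known limitations

* Linear trajectories only; a genuinely branching process will be forced
  onto one axis.
* The pseudotime start depends on the anchoring stromal signature; when the
  stromal program saturates early (flat head), the start cell is only
  localized to the flat region, and ordering within it is noise-limited.
* The GSZ's per-cell centering makes very large sets (an appreciable
  fraction of the matrix) partially self-referential; scores remain
  well-defined but shrink.
* The chi-square reference of the association test is mildly anticonservative
  at small n (see above); at n ≥ 200 the effect is negligible.
* Typology thresholds were calibrated once on the reference fixture; on
  data with substantially different noise structure the committed defaults
  may need revisiting through `typology_control()`.
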