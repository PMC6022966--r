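# ptdyn — pseudotime dynamics of single-cell expression signatures

`ptdyn` orders single cells along a one-dimensional pseudotime and tracks
how the activity of functional gene programs changes along it. It was built
for small, deeply sequenced tumour cultures (tens to a few hundred cells
with FPKM-like quantification) — the motivating system is melanoma
short-term cultures and their canonical programs (stromal, proliferation,
oxphos, glycolysis, the antagonistic MITF/AXL axis, poised/active promoter
activity) — but the machinery is generic.

The pipeline:

1. **Preprocess** — drop cells expressing neither housekeeping gene (ACTB,
   GAPDH), quantile-normalize so every cell has an identical value
   distribution.
2. **Score** — the gene set Z-score (GSZ) per cell and gene set:
   `GSZ = (S − m·μ) / sqrt(m·σ²·(N−m)/(N−1) + λ)`, the z-score of the set
   sum `S` against random same-size sets drawn without replacement from the
   cell's per-gene standardized `log2(FPKM+1)` scores.
3. **Order** — Wanderlust-style pseudotime: an ensemble of subsampled
   k-nearest-neighbour graphs (defaults k = 16, l = 8 of k kept per member,
   20 members) over full-transcriptome correlation distances; pseudotime is
   the per-cell mean shortest-path distance from a stromal-anchored start
   cell, rescaled to [0, 1] and oriented so proliferative activity rises.
   A two-segment fit of pseudotime against cell rank reports the
   characteristic breakpoint PT\* of an initial "slow" component when
   present.
4. **Profile** — LOESS-smooth each signature along pseudotime and rescale
   to relative activity in [0, 1].
5. **Test** — rank genes/sets by pseudotime dependence with a spline
   likelihood-ratio test (natural cubic spline of PT, df = 3, vs intercept;
   χ²₃ reference) under Benjamini–Hochberg FDR, split by direction.
6. **Classify** — label the geometry of pairwise signature trajectories:
   switch-like, parallel anti-correlated, divergent (across cultures),
   orthogonal, curved.

A synthetic-data module generates expression matrices with a known latent
pseudotime and temporally patterned modules (decaying stromal, delayed
cell-cycle ramp, saturating oxphos, late-rising glycolysis, bipolar
MITF/AXL, linear TssA/TssP), with log-normal noise, dropout and failed
cells — so every stage is testable against ground truth. See the methods
vignette (`vignettes/pseudotime-dynamics.Rmd`) for the models, defaults and
their rationale.

## Worked example

```r
library(ptdyn)
library(dplyr)

ds <- simulate_expression(84, modules = default_modules(), noise_sd = 0.5,
                          dropout_rate = 0.1, seed = 1)
cfg <- run_config(matrix = ds$matrix, gmt = ds$gmt, out_dir = tempfile(), seed = 1,
                  pairs = list(c("oxphos", "cellcycle"), c("TssP", "TssA")))
res <- run_pipeline(cfg)

res$pseudotime
#> <pseudotime_result> 84 cells, start 'cell_055', oriented (k = 16, l = 8, 20 graphs, correlation)
cor(res$pseudotime$pt$pt, ds$true_pt$true_pt, method = "spearman")
#> [1] 0.953

head(tidy(res$association), 4)
#> # A tibble: 4 × 6
#>   target    lr_stat    df        p      fdr direction
#>   <chr>       <dbl> <int>    <dbl>    <dbl> <chr>
#> 1 stromal      205.     3 2.89e-44 2.31e-43 anti-correlated
#> 2 AXL          179.     3 1.57e-38 6.27e-38 anti-correlated
#> 3 MITF         165.     3 1.79e-35 4.77e-35 correlated
#> 4 cellcycle    159.     3 3.18e-34 6.36e-34 correlated

res$typology[, c("set_a", "set_b", "label", "r", "leading_axis")]
#> # A tibble: 2 × 5
#>   set_a  set_b     label                        r leading_axis
#> 1 oxphos cellcycle switch_like              0.743 a
#> 2 TssP   TssA      parallel_anticorrelated -0.875 NA
```

Reading the output: the inferred ordering recovers the generator's latent
pseudotime at Spearman 0.95 under realistic noise; the stromal program is
the top anti-correlated (early, decaying) signature and cell cycle a top
correlated (late-rising) one, exactly as constructed; oxphos saturating
before proliferation takes over is read as a switch-like trajectory with
oxphos leading, and the poised/active promoter pair as a straight
anti-diagonal. `autoplot(res$pseudotime)`, `plot_profiles(res$profiles)`
and `plot_trajectory()` draw the corresponding figures, and every table is
also written as TSV (plus a provenance JSON) into the run directory.

A thin command-line wrapper over the same functions ships in
`inst/cli/ptdyn.R`:

```sh
Rscript inst/cli/ptdyn.R simulate --n-cells 84 --seed 1 --out sim/
Rscript inst/cli/ptdyn.R run --matrix sim/matrix.tsv --gmt sim/modules.gmt --seed 1 --out run/
```

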