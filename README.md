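# ringflux

Growth and water-use efficiency analysis for tree-ring chronologies.

## The problem this package addresses

At the warm, dry edge of a species' range, long-lived trees record a
century of environmental change in two complementary archives: annual
ring widths (growth) and the carbon isotope ratio of the wood
(ecophysiology). ringflux is a toolkit for dendroecologists who want to
compare groups of co-occurring trees — e.g. two oak species and their
hybrid — across contrasting climate periods, asking whether growth
rates, intrinsic water-use efficiency (iWUE), their climate drivers and
their coupling differ between groups and have changed over time.

The package covers the full analysis chain:

* **Formats** — Tucson/RWL ring-width files (both 0.01 and 0.001 mm
  dialects), CSV tables for tree metadata, wood δ¹³C, atmospheric CO₂
  history and monthly climate, with strict validation and cross-checks.
* **Chronologies** — basal area increment BAI(t) = π(r²ₜ − r²ₜ₋₁),
  group mean chronologies with sample depth, mean interseries
  correlation r̄ and the expressed population signal
  EPS = n·r̄ / (n·r̄ + 1 − r̄) with the EPS > 0.85 reliability
  convention; linear trends, 10-yr high-pass filtering and smoothing,
  inter-chronology correlations.
* **Isotopes** — discrimination Δ = (δ¹³Cₐ − δ¹³Cₚ)/(1 + δ¹³Cₚ/1000),
  intercellular CO₂ from Δ = a + (b − a)·Ci/Ca (a = 4.4 ‰, b = 27 ‰),
  iWUE = (Ca − Ci)/1.6, and the Suess correction for the fossil-fuel
  depletion of atmospheric δ¹³C.
* **Climate response** — homogenisation of a long distant record onto a
  short local one, 16 lagged seasonal predictors (DJF/MAM/JJA/SON ×
  T/P × current/previous year), and correlation screens with 95% bands.
* **Group comparisons** — Kruskal–Wallis + Nemenyi post hoc with letter
  displays; per-tree period anomalies with paired Wilcoxon tests.
* **Growth model** — gamma GLMM (log link) of BAI on standardized iWUE,
  seasonal climate and tree size with per-tree random intercepts and
  slopes; VIF ≤ 2 screening, AICc selection over a crossed model set,
  boundary-corrected LRTs for random effects, predictive-skill metrics.
* **Synthetic forest** — a generative twin of the whole study design
  with known ground truth, used to validate every module end to end.
* **Pipeline** — `run_pipeline()` chains everything with a config
  object, stage logging and a deterministic run manifest.

## Worked example

Simulate the default study design (3 genetic groups × 20 trees,
1860–2015, warming/drying climate, rising CO₂), build a chronology,
derive iWUE, and fit the growth model:

```r
library(ringflux)

forest <- generate_forest(forest_scenario(seed = 42))

# --- BAI chronology of one group over the early window ---------------
bai  <- forest$trees$bai
qupe <- bai[bai$group == "QuPe", c("tree_id", "year", "bai")]
build_chronology(qupe, "BAI", group = "QuPe", window = c(1880, 1915))
#> <chronology> BAI [QuPe]: 20 trees, 1880-1915, rbar=0.280, EPS=0.886,
#>              reliable 1880-1915
```

Twenty trees correlating pairwise at r̄ = 0.28 give EPS = 0.886 — above
the 0.85 convention, so the group mean is a reliable chronology over
this window.

```r
# --- d13C -> discrimination -> iWUE, with subperiod statistics -------
iso <- forest$isotopes$d13c
res <- iwue_chronology(iso[iso$group == "QuPe", ], forest$atmosphere,
                       windows = list(period1 = c(1880, 1915),
                                      period2 = c(1980, 2015)),
                       group = "QuPe")
res$stats[, c("window", "variable", "r", "mean", "sd", "slope")]
#>    window variable     r  mean    sd    slope
#> 1 period1     iWUE 0.500 117.3 2.480  0.17194
#> 2 period1     d13C 0.234 -18.9 0.197  0.00378
#> 3 period2     iWUE 0.832 154.4 5.980  0.53662
#> 4 period2     d13C 0.542 -20.0 0.291 -0.02186
```

iWUE rises ~0.54 µmol mol⁻¹ yr⁻¹ in the recent window (CO₂-driven),
while raw δ¹³C declines — the atmospheric Suess imprint, which the
discrimination chain accounts for via year-specific δ¹³Cₐ and Ca.

```r
# --- gamma growth model over the early window ------------------------
md  <- build_model_data(bai, forest$trees$meta, forest$seasonal,
                        forest$isotopes$truth_group, c(1880, 1915))
fit <- fit_growth_model(md, c("iwue", "SuP", "SpP", "WiT", "SuTt"),
                        random = "intercept+iwue")
fit
#> <growth_fit> bai ~ iwue + SuP + SpP + WiT + SuTt + (1 | tree_id) +
#>   (0 + iwue | tree_id) | random: intercept+iwue | n=2160 k=9
#>   logLik=-17018.69 AICc=34055.46
#>          term estimate       se       t         p
#> 1 (Intercept)  7.75558 0.027535 281.658 0.000e+00
#> 2        iwue  0.02549 0.010635   2.397 1.652e-02
#> 3         SuP  0.11788 0.006456  18.259 1.767e-74
#> 4         SpP -0.03596 0.006795  -5.292 1.209e-07
#> 5         WiT -0.11366 0.006200 -18.334 4.464e-75
#> 6        SuTt -0.05751 0.006780  -8.482 2.206e-17
#> random-effect SDs: intercept=0.2087  iwue=0.0648
#> gamma shape: 14.334
```

The scenario planted β = (0.030, 0.116, −0.046, −0.114, −0.059) on
standardized scales with random intercept/slope SDs 0.20/0.06 and gamma
shape 15 — every estimate above is within ~1 SE of its planted truth.
Positive summer precipitation and iWUE effects, negative winter-T and
lagged summer-T effects: growth helped by summer moisture and
water-use efficiency, hurt by mild winters and hot previous summers.

```r
predictive_skill(fit, seed = 1)[c("marginal_r2", "chron_r")]
#> $marginal_r2 [1] 0.1993  (fixed effects, link scale)
#> $chron_r     [1] 0.9887  (observed vs predicted year-mean chronology)
```

The full pipeline (simulate → chronologies → iWUE → climate screens →
group comparisons → GLMM) runs from one config and writes CSV/JSON
stage outputs plus a manifest with content hashes:

```r
m <- run_pipeline(run_config(outdir = "run1", scenario = "period1",
                             seed = 1))
names(m$stages)
#> [1] "simulate" "chron" "iwue" "climcorr" "groups" "glmm"
```

## Documentation

The methods vignette (`vignettes/ringflux-methods.Rmd`) describes the
models and their assumptions, the tunable parameters with units and
defaults, what the synthetic generator does and does not emulate, the
numerical choices, and known limitations.
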