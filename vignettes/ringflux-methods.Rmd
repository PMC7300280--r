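---
title: "Methods behind ringflux: growth, iWUE and their climate drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ringflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ringflux implements a complete dendroecological analysis for comparing
radial growth and intrinsic water-use efficiency (iWUE) across groups of
trees — for example, two oak species and their hybrid at a rear-edge
mountain forest — over two contrasting climate periods (by default
1880–1915, cooler and CO~2~-poor, versus 1980–2015, warmer and
CO~2~-rich). This vignette explains the models and procedures, the
parameters that matter, the synthetic study-design generator used to
validate the pipeline end to end, and the numerical choices and
limitations a user should know about.

## Growth: from ring widths to basal area increment

Raw ring widths carry a strong geometric age trend: a constant amount of
wood spread over an ever-larger circumference gives ever-thinner rings.
The package therefore converts each tree's width series to basal area
increments,

$$\mathrm{BAI}(t) = \pi\,(r_t^2 - r_{t-1}^2),$$

where $r_t$ is the cumulative radius through year $t$. BAI of a tree
growing at constant area rate is flat, and the sum of BAI over a series
equals the final basal area exactly — a conservation identity the tests
exploit. `bai_from_widths()` accepts an `initial_radius` offset for
missing piths; the default 0 assumes the pith was reached. When several
cores per tree exist, `merge_cores()` averages them to a single tree-level
series first: the analysis unit throughout is the tree.

Group chronologies are plain arithmetic means of the member trees present
in each year. Chronology quality is summarised by the mean interseries
correlation $\bar r$ (average pairwise Pearson correlation over common
years) and the expressed population signal,

$$\mathrm{EPS} = \frac{n \bar r}{n \bar r + (1 - \bar r)},$$

with the conventional reliability threshold EPS > 0.85. The *reliable
span* reported with each chronology uses the window-wide $\bar r$ with
the year-by-year sample depth — the standard dendro convention; a
year-wise $\bar r$ would be far noisier at low depth.

## The isotope chain: d13C to discrimination to iWUE

Wood carbon is depleted in ^13^C relative to the atmosphere because
diffusion through stomata and carboxylation both discriminate against the
heavy isotope. Discrimination is computed exactly, never linearised:

$$\Delta = \frac{\delta^{13}\mathrm{C}_{atm} - \delta^{13}\mathrm{C}_{plant}}
{1 + \delta^{13}\mathrm{C}_{plant}/1000},$$

with the year-specific atmospheric $\delta^{13}\mathrm{C}_{atm}$, so the
fossil-fuel depletion of the atmosphere (Suess effect) is handled inside
$\Delta$ itself. The linear model $\Delta = a + (b-a)\,C_i/C_a$ (diffusion
fractionation $a = 4.4$ ‰, carboxylation $b = 27$ ‰) is inverted for the
intercellular CO~2~ concentration $C_i$, and

$$\mathrm{iWUE} = \frac{C_a - C_i}{1.6},$$

the assimilation-to-stomatal-conductance ratio, with 1.6 the
diffusivity ratio of water vapour to CO~2~.

Two design points deserve emphasis:

* **No double correction.** Raw measured d13C feeds the $\Delta$/iWUE
  chain together with year-specific $\delta^{13}\mathrm{C}_{atm}$ and
  $C_a$. The explicit Suess correction
  (`suess_correct()`, subtracting
  $\delta^{13}\mathrm{C}_{atm}(t) - \delta^{13}\mathrm{C}_{ref}$ with a
  configurable pre-industrial reference of −6.4 ‰) is used *only* for
  display and trend work on the d13C series themselves. Feeding
  Suess-corrected values into $\Delta$ would correct twice — a known
  pitfall.
* **Out-of-range $C_i$ is flagged, not censored.** $\Delta$ outside
  $[a, b]$ maps to $C_i$ outside $[0, C_a]$; values are returned with a
  flag so that data problems surface instead of vanishing.

A caveat: with these formulas and any standard atmospheric history,
century-scale iWUE levels for oak-like d13C (≈ −19 ‰) sit near
100–150 µmol mol^−1^. Some published group means are substantially lower
than what the same formulas give for the reported mean d13C (unstated
extra processing or non-standard atmospheric inputs are the usual
suspects); ringflux computes the standard formulas and never calibrates
its outputs toward any published table.

## Climate data and the seasonal screen

Long climate series rarely exist at the study site itself.
`rescale_long_record()` merges a long, distant record into a short local
one, month by month: temperature is shifted additively and precipitation
scaled multiplicatively so that overlap-period monthly means match the
local station; local values are kept verbatim wherever they exist. The
operation is idempotent, and a month with zero long-record precipitation
falls back to an additive shift with a warning.

`seasonal_aggregate()` builds the 16 standard predictors: winter (DJF),
spring (MAM), summer (JJA) and autumn (SON) temperature means and
precipitation sums, for the current and the previous year (suffix `t`,
e.g. `SuTt` = previous-year summer temperature). Winter of year $y$ uses
December of $y-1$ — the DJF season is assigned to the year of its
January/February, the standard dendroclimatological convention.

`climate_correlation_screen()` correlates an annual chronology with each
predictor over a window, with pointwise two-sided 95% critical values
from the $t$ distribution on $n-2$ degrees of freedom. Following common
practice in the field the bands are pointwise; because 16 tests are run,
a Bonferroni-adjusted p-value column is also emitted for honesty. The
chronology (never the climate) may be pre-smoothed, either with a 10-yr
high-pass (the classic even-order centered moving average with half
weights at the ends, which removes a linear trend exactly) or with a
"10-year spline". The latter is implemented as a discrete smoothing
spline (second-difference penalty, Whittaker form) whose frequency
response is exactly 50% at a 10-year wavelength:
$\lambda = (2\sin(\pi/10))^{-4}$, giving
$H(\omega) = 1/(1+\lambda\,(2\sin(\omega/2))^4)$. On annual data this is
the same smoothing family the classic dendro spline approximates, with a
cutoff that is exact rather than asymptotic. Growth screens default to
the spline smoothing, d13C screens to no smoothing.

## Group comparisons

Growth and iWUE levels are skewed, so group comparisons are rank-based:
the tie-corrected Kruskal–Wallis omnibus test (via `stats::kruskal.test`)
followed by the Nemenyi all-pairs test on mean ranks against the
studentized-range distribution, with letter displays (groups sharing a
letter do not differ at the chosen level). Period contrasts use the tree
as the experimental unit: each tree contributes one mean per window and
the anomaly (period 2 minus period 1) is tested against zero within each
group by the paired Wilcoxon signed-rank test (years are autocorrelated,
so year-level tests would overstate the evidence), and across groups by
Kruskal–Wallis + Nemenyi.

A small-sample honesty note: the chi-squared reference for
Kruskal–Wallis is an approximation. For the balanced three-groups-of-three
design its p-value tracks the exact permutation p within 0.03 throughout
the decision-relevant tail, but in the middle of the (very discrete)
permutation distribution, and for unbalanced tiny designs, gaps up to
~0.05–0.08 are a property of the approximation itself. At the package's
default design (20 trees per group) this is immaterial.

## The gamma growth model

BAI is strictly positive and right-skewed, so growth is modelled with a
gamma GLMM with log link: observation $=$ tree × year,

$$\mathrm{BAI}_{it} \sim \Gamma\!\big(\nu,\ \mu_{it}/\nu\big),\qquad
\log \mu_{it} = \beta_0 + \mathbf{x}_{t}'\boldsymbol\beta +
(\beta_w + b_i)\,z^{\mathrm{iWUE}}_{t} + u_i,$$

with per-tree Gaussian random intercepts $u_i$ and optional random iWUE
(or climate) slopes $b_i$. Estimation maximises the Laplace-approximated
marginal likelihood (glmmTMB backend). Design choices:

* **Log link** — multiplicative climate effects on a positive response;
  the standard choice for gamma mixed models.
* **Standardised predictors** — all predictors are z-scored within the
  analysis window before fitting (seasonal variables over window years;
  the group iWUE chronology within group, because its level and trend are
  group-specific; tree size across trees). Lagged predictors are lagged
  first, then standardised. Coefficients are therefore comparable across
  predictors and across the crossed model set.
* **iWUE for non-isotope trees** — only a subset of trees has d13C
  series; all other trees take their group's iWUE chronology value. This
  keeps the predictor observable for every tree at the cost of removing
  within-group iWUE contrast; the random iWUE slope then captures
  tree-level heterogeneity of the response instead.
* **Uncorrelated random slopes** — random slopes are modelled independent
  of random intercepts (diagonal covariance). Each additional slope then
  adds exactly one variance parameter, so the boundary-corrected LRT
  (50:50 $\chi^2_0/\chi^2_1$ mixture for one variance) applies cleanly.
* **Random-free fits** — structures without random effects are fitted as
  a gamma GLM with the shape profiled out by exact maximum likelihood
  (one-dimensional root of the digamma score), so their log-likelihoods
  are directly comparable with the mixed fits in one AICc table. (The
  default GLM log-likelihood in R uses a moment-style dispersion and is
  *not* the maximised likelihood.)

### Collinearity, model set and selection

Candidate fixed effects are screened by the variance inflation factor,
computed from the inverse correlation matrix (identical to
$1/(1-R_j^2)$ from auxiliary regressions); predictors are dropped
iteratively until all VIF ≤ 2, with exact duplicates removed first
(keeping the earliest column) so the screen is deterministic.

`enumerate_and_select()` fits the crossed set of fixed-effect subsets
(capped, default ≤ 6 per model) times the requested random structures,
ranks by AICc ($\mathrm{AIC} + 2k(k+1)/(n-k-1)$), and selects the *best
and most parsimonious* model: among models within `delta` AICc units of
the minimum (default 6, the "substantial support" band of Richards
2008), the one with fewest parameters, ties broken by lower AICc. Plain
minimum-AICc selection (`delta = 0`) systematically admits noise
predictors — each irrelevant candidate sneaks into the minimum-AICc model
with probability $P(\chi^2_1 > 2) \approx 0.16$, so with five noise
candidates the exact true subset would be recovered less than half the
time; the parsimony band restores consistent subset recovery (~95% in the
package's strong-signal simulations) while never discarding real signal
of meaningful size.

The pipeline's `glmm` stage uses a two-stage shortcut: the fixed-effect
subset is chosen under the marginal (random-free) model, then the random
structures are compared on the winning subset and confirmed by the
boundary LRT. This keeps a full pipeline run in seconds; the fully
crossed enumeration remains available directly through
`enumerate_and_select()`.

### Predictive skill

`predictive_skill()` reports (i) marginal variance explained on the link
scale, $\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \sum
\hat\sigma^2_{re} + \psi_1(\hat\nu))$, using $\psi_1(\nu)$ — the exact
variance of $\log Y$ for a gamma variable — as the residual term; (ii)
the adjusted R² of observed on predicted observations; and (iii) the
Pearson correlation between observed and predicted year-mean
chronologies with a 99% flag, plus a 95% prediction band for the year
means obtained by parametric simulation from the fitted gamma model. An
intercept-only model has a constant predicted chronology; its correlation
is reported as `NA` rather than a fabricated zero.

## The synthetic forest: what it emulates, and what not

`forest_scenario()` defines a complete generative study design whose
defaults mirror the motivating field setting: three genetic groups × 20
trees over 1860–2015, 5 isotope trees per group, a Mediterranean-mountain
climatology (window-1 mean annual temperature 5.7 °C warming by
1.3 °C per century; annual precipitation 1200 mm drying by ~100 mm per
century, summer-dry seasonal cycle), a monotone logistic CO~2~ path
pinned to 288–400.5 ppm (window means ~294 and ~379 ppm, inside the
290–302 and 338–400 ppm ranges of the two periods) with the matching
linear-in-Ca decline of atmospheric d13C from −6.4 to −8.4 ‰, per-group
baseline d13C of −18.6/−19.4/−19.6 ‰ with a +0.25 ‰/°C summer-temperature
sensitivity, and gamma-distributed BAI (shape 15, exp(7.75) ≈ 2300 mm²
yr^−1^ baseline) driven by standardised seasonal climate and iWUE with
per-tree random intercepts (SD 0.20) and iWUE slopes (SD 0.06). The
planted coefficient vector of the default ("period-1-like") scenario and
of `scenario_period2()` uses published-magnitude standardized
coefficients as scenario parameters — they are planted truths for
recovery testing, not reproduction claims.

Climate anomalies have a two-layer structure: a weak shared AR(1) annual
effect (0.3 °C, 10% precipitation) plus dominant independent monthly
noise (0.9 °C, 25%), giving cross-season correlations around 0.2–0.3 as
in real monthly records. An earlier single-shared-year-effect design was
rejected because it produced cross-season correlations near 0.9, which no
real climate record shows and which makes any VIF screen discard true
predictors. Noise levels were chosen once so that the default chronology
$\bar r$ falls in the 0.2–0.4 band typical of temperate oak BAI
chronologies, putting EPS near the 0.85 reliability boundary — the
interesting regime for testing.

Everything is generated by inversion of the package's own definitions:
ring widths invert the cumulative disc-area relation
($w_t = \sqrt{r_{t-1}^2 + \mathrm{BAI}_t/\pi} - r_{t-1}$), measured d13C
inverts the discrimination chain through the year's atmosphere. The
analysis modules applied to generator output therefore recover the
planted BAI and iWUE *exactly* (to float precision), which the tests
assert at 10^−9^. The long climate record is the exact constant-offset /
constant-ratio transform of the truth, so homogenisation is also exactly
invertible.

What the generator does **not** emulate — and hence what green tests do
not show about real data: crossdating error, missing or locally absent
rings, juvenile growth phases and age trends beyond pure geometry,
disturbance pulses and canopy dynamics, autocorrelated growth residuals
(residuals are conditionally independent gamma draws), post-photosynthetic
isotope fractionation, and measurement error in the climate records. The
tree-size covariate written to the metadata is the realised final
diameter, so in scenarios with a planted size effect the fitted DBH
coefficient is attenuated relative to the planted latent-size effect;
parameter-recovery tests therefore target the climate and iWUE
coefficients. In the default scenario, DBH still enters selected models
legitimately: final size is informative about the per-tree random
intercept.

## Numerical choices, degenerate inputs, reproducibility

* Pearson p-values use the $t$ approximation with no autocorrelation
  correction, matching how significance bands are conventionally drawn in
  climate-response figures.
* The RWL reader auto-detects the 0.01 mm (terminator 999) and 0.001 mm
  (terminator −9999) dialects per series; the writer defaults to
  0.001 mm. Round-trips are bit-exact at the declared precision. Missing
  rings (width 0) are retained and contribute BAI 0.
* Degenerate inputs are defined, not crashed: identical pooled values
  give $H = 0, p = 1$; EPS with a non-positive denominator returns `NA`
  (not reliable) with a warning; a constant predicted chronology gives
  `NA` correlation; boundary mixed fits (a variance estimated at ~0)
  report the optimiser's objective as the log-likelihood when the
  Hessian is not positive definite, with the diagnostic retained in the
  fit object.
* All randomness flows from explicit seeds through `with_seed()`, which
  restores the RNG state afterwards; `run_pipeline()` derives every
  stochastic stage from the single config seed, and two runs with the
  same config are bit-identical (the manifest records md5 hashes of every
  output and excludes wall-clock information on purpose).
* Problem sizes in the test-suite simulations (e.g. 100 recovery
  replicates of the full 60-tree design, 200 LRT-calibration replicates
  of a reduced 24-tree design, 50 selection replicates at n = 600) were
  chosen as the smallest sizes at which the Monte Carlo error is clearly
  below the property margins being asserted.

## Known limitations

Bootstrap response functions, moving-window correlation evolution,
drought indices, detrending alternatives to BAI (RCS, splines),
autoregressive chronology standardisation, mesophyll-conductance
extensions of the discrimination model and Bayesian estimation are out of
scope. The Nemenyi test uses the large-sample studentized-range variant
for unequal group sizes; for very small unbalanced groups an exact
permutation approach would be preferable. Genetic group labels are taken
as given inputs; the package does not re-derive them.
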