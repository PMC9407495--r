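---
title: "From annual climate to flavonoids to peel color: methods and design"
author: "peelpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From annual climate to flavonoids to peel color: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peelpath)
```

## The scientific problem

Peel color of Chinese prickly ash (*Zanthoxylum bungeanum*) is a quality
trait that varies strongly with provenance. The working hypothesis this
package operationalizes is a causal chain: annual climate (temperature,
humidity, precipitation, wind, sunshine) shapes the accumulation of
flavonoid and anthocyanin pigments in the peel, and those pigments — plus
some direct climatic influence — determine the CIELAB color coordinates
L\* (lightness), a\* (green–red) and b\* (blue–yellow). The package
provides every statistical stage of that inference as a tested, reusable
function: correlation screening, multivariate chemotyping (PCA, HCA,
OPLS-DA), stepwise-screened path analysis with decision coefficients,
content-on-color regression, and covariance-based structural equation
models (SEM) with effect decomposition and fit-index model selection.

Two data sources drive everything:

* the bundled quantification fixture (`load_table1_fixture()`): 26 peel
  provenances x 15 analytes, mean ± SD in mg/g of dried peel; and
* the synthetic generator (`generate_samples()`), which realizes the
  full altitude → climate → flavonoid → color chain with known
  standardized coefficients, so recovery of "truth" can be measured.

The provenance-level climate and color measurements behind the original
study are not publicly deposited; analyses that need them run on
synthetic tables, while printed summary coefficients are used as exact
arithmetic checks.

## The synthetic generator

`default_synth_config()` encodes the study conditions: 6 geographic
groups occupying contiguous altitude bands over 201–2188 m, 26 samples
in total. All structural equations are linear with independent Gaussian
noise. Internally every variable is built in standardized units —
altitude is uniform over its range (variance 1 after scaling), each
climate factor is `slope * z_altitude + noise`, each flavonoid a sparse
linear combination of climate factors, each color axis a combination of
direct climate effects and flavonoid loadings. Noise SDs left `NA` are
completed automatically so each variable has unit variance, which makes
the configured coefficients *be* the standardized path coefficients.
Presentation units are applied afterwards by fixed affine scales (e.g.
L\* centered at 83 with scale 2.5, which keeps the noiseless lightness
inside the observed 73–93 band); affine maps leave correlations and
standardized paths untouched.

Default path magnitudes are seeded from the study-scale standardized
coefficients where a coherent joint model allows it: mean maximum
temperature → cyanidin 3-O-glucoside −0.50 and maximum wind → +0.41;
maximum wind → peonidin 3-O-glucoside 0.45; peonidin glucoside → L\*
0.75 with a direct wind effect 0.21; quercitrin → b\* −0.77. The
published a\*-equation coefficients (−0.46, 0.36 direct plus 0.88 via
the anthocyanin) are mutually inconsistent with unit variances — their
implied variance exceeds one for any admissible exogenous correlation —
so the a\* defaults keep the mediated path dominant (0.75) and shrink
the direct climate edges (−0.15, 0.12). The generator refuses any
configuration whose implied standardized variance reaches 1, which also
guarantees a positive-definite implied covariance
(`synth_implied_correlation()`).

What the generator does *not* emulate: within-sample analytical
replicates (the fixture's n = 3 triplicates), non-Gaussian or nonlinear
climate responses, spatial autocorrelation beyond the shared altitude
driver, and group-level random effects (groups are altitude bands, not
random factors). Passing recovery tests therefore demonstrate
correctness of the estimators under the linear-Gaussian model the SEM
itself assumes — not robustness to real-world violations of it.

## Correlation screening

`pearson_matrix()` uses pairwise-complete observations (so partial
tables load and correlate), exact two-sided t-based p-values
(`t = r sqrt((n-2)/(1-r^2))`, n−2 df — the normal approximation is poor
at n = 26), and the field's star convention: `**` for p < 0.01, `*` for
0.01 ≤ p < 0.05, strict inequalities, no multiple-testing correction
(the convention the screened tables use; correct afterwards with
`p.adjust` if desired). Constant columns give `NA` with a warning, never
a silent 0.

## Multivariate chemotyping

PCA is computed by SVD of the column-centered matrix. The default
scaling is unit variance: analyte contents span two orders of magnitude,
and the clustered heatmap convention in this field z-scores variables.
On the bundled fixture this reproduces the reported PC1 share (48.6%
computed vs 48.36% reported). The reported PC2 (14.59%) is about 0.8
points above what the 26 printed means give (13.76%) under any scaling
we examined (unit-variance, covariance, Pareto, log); the likeliest
explanation is that the original analysis used the 78 analytical
replicates or additional columns, neither of which is recoverable. The
discrepancy is carried, documented, in the acceptance suite rather than
absorbed by a wider tolerance.

HCA z-scores variables, then clusters samples on Euclidean distances
with complete linkage by default (ward.D2 and average are available);
the source analysis states unit-variance scaling but not the linkage, so
the A-group-cohesion check on the fixture documents the default rather
than a known setting. Dendrograms export to newick via `ape`.

OPLS-DA follows the orthogonal-projection construction: class coded
±1 and centered, predictive weight `w ∝ X'y`, and each orthogonal
component removes from X the part of its loading orthogonal to `w`.
Because the class covariance of every orthogonal score is exactly zero
by construction, that invariant is asserted to 1e-10. With zero
orthogonal components the procedure reduces to single-component PLS-DA
(tested against a direct PLS computation). Q² uses stratified 7-fold
cross-validation — a conventional OPLS-DA default, seeded for
reproducibility. Note that with a single informative variable among
noise variables, the predictive score recovers class membership near
perfectly but not infallibly; the misclassification rate is the price of
the noise directions entering `X'y`.

## Path analysis and decision coefficients

For a response y and screened predictors, the direct path coefficients
are the standardized regression coefficients P solving
`R_xx P = r_xy`; the indirect effect of predictor i via co-predictor j
is `r_ij P_j`, so each correlation decomposes exactly:

    r_xy(i) = P_i + sum_{j != i} r_ij P_j

This identity holds to machine precision and is property-tested on 1000
random positive-definite systems. The decision coefficient

    D_i = 2 P_i r_xy(i) - P_i^2

ranks predictors by their net effect (positive = promoting, negative =
inhibiting). The formula is not printed in the source literature; it was
locked by verifying six internally consistent printed cells (0.518,
0.531, 0.157, −0.093, 0.227, 0.312 at 3 d.p.) before the build.
`path_decompose()` also accepts correlation-level inputs so printed path
tables can be checked without raw data. Direct coefficients with
magnitude above 1 are legal (they occur in the published table under
strong collinearity) but trigger a warning.

Stepwise screening (`stepwise_select()`) is the classic SPSS-style
procedure the original workflow implies: forward entry of the smallest
partial-F p-value below `p_enter` (default 0.05), backward removal above
`p_remove` (default 0.10), deterministic tie-breaks by candidate order.
Two statistical facts are worth stating because they bound what the
procedure can do: with ~10 null candidates tested each step, *some*
noise variable enters with probability ≈ 1 − 0.95^10 ≈ 40%, so the
final set equals the true set only ~60% of the time even when the true
predictor is always found; and each individual null candidate is kept at
roughly the entry rate α. The tests assert exactly these calibrated
properties (true-predictor recovery ≥ 95%, per-candidate null inclusion
≈ α), not an unattainable exact-set frequency.

## Content-on-color regression

`fit_color_regression()` regresses an analyte content on the chromatic
axes a\* and b\* (raw CIELAB units, no standardization; L\* can be
added), reporting R, R², and `F = (R²/k)/((1−R²)/(n−k−1))`. The
published seven-row regression table is used as a consistency oracle:
each printed F is reproduced from a printed R² at n = 26, k = 2 within
3-d.p. rounding slack — with the caveat that the four anthocyanin rows'
F values are printed pairwise transposed (the F implied by the peonidin
O-hexoside R² appears in the cyanidin glucoside row and vice versa, and
likewise for the peonidin glucoside / cyanidin syringic pair). The
consistency test matches each F to the row it arithmetically belongs to
and documents the transposition rather than asserting the impossible.

## Structural equation models

`fit_sem()` fits observed-variable path models (the latent "climate" /
"flavonoid" blocks of the conceptual diagram are treated as grouping,
not as measurement models) by minimizing the normal-theory ML
discrepancy

    F = ln|Σ(θ)| + tr(S Σ(θ)^{-1}) - ln|S| - p

with `Σ(θ) = (I-A)^{-1} Ψ (I-A)^{-T}`. Numerical choices: variances are
optimized on the log scale (positivity without constraints), start
values are least-squares estimates (per-endogenous OLS from S), BFGS
with tight relative tolerance, convergence declared at gradient norm
< 1e-6 with up to five jittered restarts otherwise. The chi-square uses
the (n−1) Wishart multiplier. Standard errors come from the inverse
expected information (computed with central-difference derivatives of
Σ(θ)); Wald p-values drive the `*`/`**`/`ns` edge annotations.
Standardization multiplies each coefficient by sd(source)/sd(target)
under the *model-implied* covariance, which makes the standardized
output exactly scale-invariant (tested).

Fit indices follow the standard definitions (CMIN/DF, RMSEA with the
max(χ²−df, 0) clamp, GFI/AGFI from the weighted residual traces), and
`select_models()` applies the strict thresholds CMIN/DF < 1,
RMSEA < 0.08, AGFI > 0.9; df = 0 models have undefined chi-square
indices and always fail selection. Effects decomposition reads total
effects from `(I−B)^{-1} − I` on the standardized coefficient matrix;
per-mediator contributions attribute each multi-edge path to its first
intermediate node, which reduces to the familiar product of two edges
for single-mediator chains and always sums to the indirect effect
(tested against exhaustive path enumeration). Two printed indirect
products in the source ("−0.49 = 0.66 × 0.75" and "−0.41 = −0.53 ×
−0.77") are sign-inconsistent as printed and are excluded from the
arithmetic checks.

Parameter recovery under the generator's default a\*-model structure
(n = 500, 200 replicates) shows |bias| < 0.03 and RMSE < 0.08 for all
standardized paths — the sizes used throughout the test suite, chosen to
characterize the estimator well at desk scale.

## Worked example

```{r example, eval = FALSE}
out <- generate_samples(default_synth_config(seed = 7))
cr  <- pearson_matrix(out$table, c("X_AMAT", "X_MAW", "Y_CGC", "a"))
fit <- fit_sem(out$table, parse_sem_spec("
  X_AMAT -> Y_CGC
  X_MAW  -> Y_CGC
  Y_CGC  -> a
  X_AMAT -> a
  X_MAW  -> a
  X_AMAT ~~ X_MAW"))
effects_decomposition(fit)
```

## Known limitations

* Observed variables only: no latent measurement models, no FIML for
  missing data, no robust (GLS/WLSMV) estimators, no bootstrap CIs for
  indirect effects.
* The exact published correlation and path tables depend on undeposited
  climate/color raw data and are checked only through their internally
  consistent printed cells.
* Stepwise screening inherits the multiple-testing behaviour of
  per-coefficient entry tests; it screens, it does not control
  family-wise error.
* At n = 26 an SEM with ~10 free parameters is small-sample territory;
  `fit_sem()` warns when n < 5 × free parameters, and inferences at that
  size should lean on the fit indices and on replication, not on
  individual p-values.
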