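# peelpath

Statistical pipeline for tracing how annual climate shapes flavonoid
accumulation and CIELAB peel color in fruit peels sampled along an
altitude gradient — built around the quantification of 15 flavonoid and
anthocyanin pigments in 26 provenances of Chinese prickly ash
(*Zanthoxylum bungeanum*) peel, for ecologists, phytochemists and
quality-evaluation workflows that relate metabolite profiles to
environment and color.

The package covers the full inference chain:

* **Sample tables** — schema-validated CSV/TSV reader/writer for
  provenance tables (analyte contents in mg/g, CIELAB `L`/`a`/`b`,
  10 annual climate factors), plus the bundled 26 x 15 quantification
  fixture (`load_table1_fixture()`).
* **Synthetic data with known truth** — a linear-Gaussian generator for
  the causal chain altitude → climate → flavonoids → color
  (`generate_samples()`), returning the generating standardized paths so
  recovery can be measured.
* **Correlation screening** — pairwise-complete Pearson matrices with
  exact t-based p-values and the `*`/`**` flag convention
  (`pearson_matrix()`).
* **Chemotyping** — unit-variance PCA (`run_pca()`), hierarchical
  clustering with newick export (`run_hca()`, `export_newick()`), and
  OPLS-DA with stratified cross-validated Q² (`run_oplsda()`).
* **Path analysis** — SPSS-style stepwise screening
  (`stepwise_select()`), exact decomposition of each predictor–response
  correlation into direct and per-mediator indirect path coefficients
  (`path_decompose()`), and decision-coefficient ranking
  `D = 2Pr − P²` (`decision_coefficient()`, `rank_factors()`).
* **Color regression** — content `~ a* + b*` ordinary least squares with
  R, R², F and prediction (`fit_color_regression()`,
  `predict_content()`).
* **Structural equation models** — observed-variable path models fitted
  by maximum likelihood on the sample covariance
  (`F = ln|Σ(θ)| + tr(SΣ⁻¹) − ln|S| − p`), standardized coefficients,
  CMIN/DF, RMSEA, GFI/AGFI, direct/indirect/total effect decomposition
  and threshold-based model selection (`fit_sem()`,
  `effects_decomposition()`, `select_models()`).
* **Orchestration** — `run_pipeline()` executes the stages in dependency
  order and writes a manifest; `make_report()` assembles one document.

## Worked example

Ranges and PCA on the bundled quantification table:

```r
library(peelpath)
tab <- load_table1_fixture()
summarize_ranges(tab, c("Y_QI", "Y_HY"))
#>   variable  min   max     mean which_min which_max
#> 1     Y_QI 7.55 45.13 19.82077        E4        A6
#> 2     Y_HY 6.03 27.84 14.08615        E3        A2

pc <- run_pca(tab, analyte_catalog()$code)
round(pc$explained_pct[1:3], 2)
#>   PC1   PC2   PC3
#> 48.58 13.76  9.34
```

Quercitrin (`Y_QI`) is the dominant analyte, spanning 7.55–45.13 mg/g
across provenances, and the first principal component of the z-scored
15-analyte profile carries 48.6% of the variance — the axis separating
high-altitude from low-altitude chemotypes.

Path decomposition straight from correlation-level inputs (apigenin on
mean maximum temperature and sunshine duration):

```r
path_decompose(response = "Y_AP", predictors = c("X_AMAT", "X_ASD"),
               r_xy = c(-0.470, -0.173),
               R_xx = matrix(c(1, -0.484, -0.484, 1), 2))
#> Path analysis for response Y_AP
#>             r direct indirect_total decision  p
#> X_AMAT -0.470 -0.723          0.253    0.157 NA
#> X_ASD  -0.173 -0.523          0.350   -0.093 NA
```

Each correlation splits exactly into `direct + indirect`; the decision
coefficient ranks mean maximum temperature as the net promoting factor
(D = 0.157) and sunshine duration as net inhibiting (D = −0.093).

An SEM on synthetic data with known truth (cyanidin glucoside mediating
climate effects on peel redness a\*):

```r
out <- generate_samples(default_synth_config(seed = 7))
fit <- fit_sem(out$table, parse_sem_spec("
  X_AMAT -> Y_CGC
  X_MAW  -> Y_CGC
  Y_CGC  -> a
  X_AMAT -> a
  X_MAW  -> a
  X_AMAT ~~ X_MAW"))
sem_edge_table(fit)
#>              source target standardized            p stars
#> Y_CGC~X_AMAT X_AMAT  Y_CGC  -0.55891501 2.278335e-05    **
#> Y_CGC~X_MAW   X_MAW  Y_CGC   0.38327601 3.676798e-03    **
#> a~Y_CGC       Y_CGC      a   0.61563952 6.564297e-09    **
#> a~X_AMAT     X_AMAT      a  -0.03286569 7.202001e-01    ns
#> a~X_MAW       X_MAW      a   0.39989256 7.852099e-07    **

effect_of(effects_decomposition(fit), "X_AMAT", "a")[c("direct", "indirect")]
#> $direct
#> [1] -0.03286569
#> $indirect
#> [1] -0.3440902
```

At n = 26 the estimates scatter around the generating values
(−0.50, 0.41, 0.75, −0.15, 0.12); the indirect temperature → redness
effect runs through the anthocyanin, as the mediation structure
prescribes. See `vignette("climate-flavonoid-color")` for the model
details, defaults and limitations.

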