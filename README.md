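# baybloom

Trend and bloom-phenology analysis for multi-decadal **weekly estuarine
chlorophyll-*a* records** with realistic missingness. The package is aimed
at analysts of long-running plankton monitoring programs who need to answer
three questions from gappy weekly data: has biomass declined, which
environmental drivers predict it, and has bloom timing shifted — without
letting the answer depend on how the gaps were filled.

## What it does

1. **Gap filling** — a Bayesian dynamic linear model per variable
   (local linear trend + trigonometric period-52 seasonal,
   discount-factor evolution, conjugate observation-variance learning).
   Forward-filtering backward-sampling draws *M* complete chlorophyll
   series from the joint posterior predictive:
   y_t = F′θ_t + v_t, θ_t = Gθ_{t−1} + w_t, with observed weeks kept
   verbatim.
2. **SARIMAX Monte Carlo** — a (2,0,1)×(0,1,1)₅₂ regression-with-SARIMA-
   errors model of weekly chlorophyll on lagged drivers (NH₄ lags 0–2,
   SiO₄ 0–1, NO₃/₂ 0–3, Secchi, temperature, salinity 0–2), fit to every
   imputed series; coefficients are pooled as MC mean ± MC SD plus a
   significance frequency out of *M* — terms that stay significant across
   all imputations are robust to the missing data.
3. **Granger screening** — two-regression F tests (lag order by AIC of
   the restricted model) of driver → chlorophyll predictivity on annual,
   first-differenced series, with a weekly-resolution option.
4. **Bloom phenology** — blooms are maximal runs of weeks above
   1.05 × the year's median chlorophyll; start / peak / duration /
   frequency per seasonal window (winter–spring weeks 1–16, summer–fall
   22–38), per ensemble member, with Poisson-GLM and days-per-decade
   trend tests.
5. **Trend statistics** — annual aggregates (cumulative, CV, max, min),
   Welch decade comparisons, log-linear fits, decadal weekly
   climatologies, and the Scholz–Stephens k-sample Anderson–Darling test
   (midrank ties; asymptotic or permutation p).

A seeded synthetic generator (`generate_panel()` + `apply_missingness()`)
produces 50-year weekly panels with bimodal log-scale seasonality, a slow
decline, driver-wired chlorophyll, and point / biweekly / multi-year-block
gaps, plus the ground truth needed for recovery and calibration tests.

See `vignettes/baybloom-methods.Rmd` for the full model account and
design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic panel and write tables under `results/analysis/`. A condensed
session:

```r
library(baybloom)

cfg   <- synth_config(seed = 1)                 # 50 y weekly panel, 1970-2019
gen   <- generate_panel(cfg)
panel <- apply_missingness(gen$panel, cfg)      # ~21% of chl weeks missing

imp <- impute_panel(panel, target = "chl", M = 100, seed = 2)
mc  <- run_mc(imp$ensemble, imp$panel, sarimax_order(), default_exog_spec(),
              method = "css", report_m = 100)
head(mc$summary)
```

Running `analysis/01_simulate.R` … `06_trends.R` prints (seed 1):

```
chlorophyll observed 2058 / 2600 weeks (20.8% missing)
median member SD inside 1995-1998 block gap: 4.72 vs 1.91 elsewhere
fit 99 members (1 dropped)
robustly significant terms (>=95/100): SMA1        # no32_lag1 at 87/100
winter-spring peak             8.2 +- 2.1 wk
summer-fall peak              31.1 +- 3.2 wk
annual bloom count: median 7 (range 4-10)
cumulative annual chl: -32% change first->last decade (t = 5.27, p = 0.0003)
bloom intensity (annual max): -42% change (t = 3.28, p = 0.0062)
log annual max trend: slope -0.014 /yr (R2 = 0.31, p = 2.9e-05)
pairwise decadal AD tests: 6 of 10 pairs differ at p<0.001
```

Reading this: the imputation spread is ~2.5× wider inside the four-year
block gap than at isolated gaps — that extra uncertainty is carried into
every later stage rather than hidden. The Monte-Carlo SARIMAX finds the
lag-1 nitrate+nitrite term significant in 87 of 100 imputations (the
generator wires chlorophyll to lagged NO₃/₂, so this is the right
answer), the bloom peaks land on the configured week-8 / week-32
climatology, and the built-in decline shows up as a significant drop in
cumulative annual chlorophyll between the first and last complete
decades.

To run on real data instead, write your record in the panel-CSV layout
(`year,week,chl,temp,salinity,secchi,light,precip,strat,no32,nh4,po4,sio4`,
empty cell = missing) and point `pipeline_config(panel_path = ...)` or
`read_panel()` at it.

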