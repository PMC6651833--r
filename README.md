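# bbpcarbon

Ocean carbon stocks are routinely estimated from the particulate
backscattering coefficient b_bp(λ) through empirical linear models, and
the coefficients of those models depend on which linear regression is used
to fit them. `bbpcarbon` quantifies that dependence end to end: it
implements type-I (ordinary least squares, OLS) and type-II (standard
major axis SMA, major axis MA, ranged major axis RMA) regression with
standard errors and a correlation-significance gate, derives the
bio-optical carbon model parameters from match-up data under each method,
applies them to profile and gridded time series, and measures the impact
of the method choice on the resulting carbon budgets. It is written for
bio-optical and satellite oceanographers who fit TChla–b_bp or b_bp–POC
relationships and need to know — in mg C, not in abstract slope units —
what an unsuitable regression method costs.

## The models

**Regression.** For paired observations the line `y = B·x + A` can be fit
by OLS (minimizes vertical deviations; appropriate for predicting y from
an error-free x), SMA (`B = sign(r)·s_y/s_x`; appropriate when both
variables carry comparable error and the slope itself is the target), MA
(minimizes perpendicular distances) or RMA (MA on range-normalized data).
All pass through the centroid and share r²; they disagree exactly as much
as the correlation falls short of 1 (`B_SMA = B_OLS/|r|`). When x is noisy
the OLS slope is attenuated by `Var(x*)/(Var(x*) + Var(e_x))` (regression
dilution), which is what makes the choice consequential.

**Phytoplankton carbon.** `C_phyto = (b_bp(λ) − b^k_bp(λ)) · SF`, where
`b^k_bp` is the background backscattering of non-algal particles — the
intercept of the TChla→b_bp fit, i.e., the b_bp remaining at zero
chlorophyll — and SF (mg C m⁻²) is calibrated so the mean Chl:C ratio over
the match-ups equals 0.010. This relation is asymmetric (chlorophyll
drives backscattering), so OLS is the appropriate method for `b^k_bp`;
using SMA systematically lowers the intercept and inflates every C_phyto
estimate by the constant `(b^k_bp,OLS − b^k_bp,SMA)·SF`.

**Particulate organic carbon.** `POC = B·b_bp(λ) + A`, a symmetric
relation with comparable errors on both axes, for which SMA is the
appropriate method and OLS the unsuitable comparator.

**Impact statistics.** Anomalies (unsuitable − suitable estimate,
per point) and the relative percent difference
`RPD = 100·(unsuitable − suitable)/suitable` of depth- and
time-integrated budgets (trapezoidal in both axes, on the native
irregular grids).

Because the cruise, float and satellite archives behind such analyses are
not redistributable, the package ships seeded synthetic generators that
emulate them: bottle match-ups with noise on both axes, float b_bp(700)
profiles on the three-segment float grid (10 m below 250 m, 1 m from 250
to 10 m, 0.2 m above 10 m) with injected positive spikes for QC testing,
and monthly satellite-like TChla/b_bp(443) series tuned to a prescribed
r². All generators record their truth for exact scoring.

## Worked example

```r
library(bbpcarbon)

# cruise-like TChla–b_bp match-ups, then the two fits side by side
chl <- matchups_bivariate(gen_matchups(tchla_bbp_scenario(seed = 7, n = 300)))
fit_methods(chl, c("OLS", "SMA"))
#>   method           B            A         se_B         se_A         r        r2   n
#> 1    OLS 0.005918553 0.0006080619 8.886991e-05 6.330492e-05 0.9680091 0.9370416 300
#> 2    SMA 0.006114150 0.0005140285 8.886991e-05 6.358447e-05 0.9680091 0.9370416 300
```

Even at r² = 0.94 the SMA intercept (5.1×10⁻⁴ m⁻¹) sits below the OLS one
(6.1×10⁻⁴ m⁻¹): SMA divides the attenuated OLS slope by |r|, steepening
the line and pulling the intercept down. That difference is the background
backscattering `b^k_bp`, so it propagates into every C_phyto estimate.
The full chain:

```r
rep <- run_reference_analysis(seed = 7)
rep
#> <carbon_method_report> seed 7
#>   cruise bbp_k: OLS 0.0006907, SMA 0.0005559 m-1; SF 24279 mg C m-2
#>   float C_phyto RPD +75.0%; POC RPD +1.3%; ratio RPD +72.7%
#>   cruise C_phyto RPD +187.5%
#>   satellite: r2 0.560, mean diff 2.94 mg C m-3 (33.6% of mean)
```

Reading this: deriving `b^k_bp` with SMA instead of OLS overestimates the
depth/time-integrated phytoplankton carbon of the float series by 75%
(the positive sign marks an overestimate by the unsuitable method), while
the POC budget — where the anomaly varies with b_bp and largely cancels —
shifts by only ~1%. On the satellite-like monthly series (r² tuned to
0.56) the SMA-based C_phyto exceeds the OLS-based one by 2.94 mg C m⁻³ on
average, a third of the mean stock. The C_phyto RPDs are strongly
data-dependent: they scale with the constant anomaly `Δb^k_bp·SF` relative
to the mean C_phyto of the series, which is small whenever deep,
low-signal water dominates the integration range.

## The analysis workflow

The `analysis/` directory holds the four-stage narrative pipeline, each a
thin driver over the package functions, writing tables, parameter files
and figures under `results/`:

1. `01_simulate.R` — generate the synthetic cruise match-ups, float
   series, cruise casts and satellite series (with truth sidecars).
2. `02_qc_and_fit.R` — despike the float series; fit both relationships
   with all four methods; scatter-plus-lines figures.
3. `03_carbon_models.R` — derive `b^k_bp` under OLS and SMA, calibrate
   SF, fit the POC model both ways, write parameter JSONs.
4. `04_budget_comparison.R` — budgets and anomalies under both
   parameterizations for the float, cruise and satellite series.

Run them in order from the repository root with `Rscript`.

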