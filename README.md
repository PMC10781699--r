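# aquarisk

Heavy-metal pollution indices and probabilistic human health risk for
water surveys.

`aquarisk` is for hydrogeochemists and environmental-health analysts who
have a per-sample water-chemistry table — major ions plus the eight heavy
metals Cd, Cr, Cu, Fe, Mn, Ni, Pb, Zn in mg/L — and need the standard
contamination and health-risk workup:

* **Pollution indices.** Heavy metal pollution index
  HPI = ΣWᵢQᵢ / ΣWᵢ with sub-index Qᵢ = 100 Cᵢ/Sᵢ and weight Wᵢ = 1/Sᵢ,
  and metal index MI = Σ Cᵢ/UALᵢ, each with its conventional
  classification scale (HPI > 100 unsuitable; MI > 6 severely affected).
* **Deterministic risk (USEPA model).** Chronic daily intake by ingestion,
  CDI = C·IR·EF·ED/(BW·AT), and by skin contact,
  CDI = C·ET·EF·Kp·SA·CF·ED/(BW·AT); hazard quotient HQ = CDI/RfD with the
  route-matched reference dose (RfD_dermal = RfD_oral × ABS); hazard index
  HI = ΣHQ; carcinogenic risk CR = CDI × CSF for Cd, Cr, Pb. Adult and
  child receptors, strict decision rules HI > 1 and CR > 1×10⁻⁴.
* **Probabilistic risk.** Seeded Monte Carlo propagation of concentration
  uncertainty (truncated-lognormal fits to survey summary statistics by
  default) through the same equations, reporting means, 5th/50th/95th
  percentiles and threshold-exceedance fractions.
* **Hydrochemistry.** TDS by ion summation, ionic balance error,
  chloro-alkaline index CAI-I, salinity classes, Sulin genetic water types.
* **Synthetic surveys.** A generator that emulates a 133-sample
  desert-oasis survey (aquifer wells, springs, hypersaline lake/drain
  samples) from published min/max/mean/sd statistics and Pearson
  correlations, via truncated-lognormal marginals and a calibrated
  Gaussian copula, with per-sample charge balance within ±5%.

The methods vignette (`vignettes/heavy-metal-risk-methods.Rmd`) documents
the models, every tunable constant with its units, and the design choices.

## Worked example

```r
library(aquarisk)

sv  <- generate_survey(generator_config(seed = 1))   # 133-sample survey
idx <- summarize_indices(sv)
rt  <- risk_table(sv)
combined_report(idx$summary, rt$summary)
```

The report is the classification table (excerpt):

```
          criteria       min       max      mean    range             class      samples
                MI 4.638e+00 4.681e+02 7.123e+01 MI < 0.3        very_clean     0 (0.0%)
                          NA        NA        NA   MI > 6 severely_affected  132 (99.2%)
               HPI 1.931e+02 6.512e+03 1.733e+03     < 25         excellent     0 (0.0%)
                          NA        NA        NA    > 100        unsuitable 133 (100.0%)
   HI Adult (Oral) 9.162e-01 1.195e+02 1.641e+01      < 1          low_risk     1 (0.8%)
                          NA        NA        NA      > 1         high_risk  132 (99.2%)
 CRCd Adult (Oral) 1.216e-03 3.477e-02 8.255e-03  < 1e-04        acceptable     0 (0.0%)
                          NA        NA        NA  > 1e-04         high_risk 133 (100.0%)
```

Read: this synthetic survey is polluted throughout — every sample's HPI
exceeds 100 (unsuitable for drinking), the mean HPI is ≈1.7×10³, 99.2% of
samples are severely metal-affected (MI > 6), oral exposure gives nearly
every sample a hazard index above 1 for adults, and the cadmium
carcinogenic risk exceeds the 1×10⁻⁴ acceptability threshold in all
samples.

Probabilistic risk for one metal:

```r
simulate_risk(
  specs    = list(fit_distribution(0.04, 0.03, 0.002, 0.19, metal = "Cd")),
  receptor = "child", route = "oral", endpoint = "CR",
  n_iter   = 10000, seed = 1)
#>  metal receptor route endpoint n_iter seed   mean      p5    p50    p95 frac_exceed
#>     Cd    child  oral       CR  10000    1 0.0277 0.00741 0.0222 0.0669           1
```

A child drinking water whose Cd concentration follows the fitted truncated
lognormal (mean 0.04, sd 0.03, bounds [0.002, 0.19] mg/L) carries a median
lifetime cancer-risk increment of ≈0.022, with a 90% band of
0.0074–0.067; every draw exceeds the 1×10⁻⁴ acceptability level.

The full pipeline — survey (file or synthetic), hydrochemical summary,
indices, deterministic risk, Monte Carlo, combined report, run log — is one
call:

```r
run_pipeline("out/", n = 133, seed = 1)
```

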