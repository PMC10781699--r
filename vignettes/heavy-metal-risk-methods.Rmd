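---
title: "Heavy-metal water quality and health risk: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal water quality and health risk: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

aquarisk assesses heavy-metal contamination of surface water and groundwater
and the human health risk it implies. It was built around the kind of survey
run in arid, groundwater-dependent settings — a desert oasis whose carbonate
aquifer wells, springs and terminal salt lakes span brackish to hypersaline
water — but every stage operates on any per-sample table of major ions and
the eight metals Cd, Cr, Cu, Fe, Mn, Ni, Pb, Zn (all mg/L).

## Pollution indices

For metal $i$ with concentration $C_i$ and drinking-water standard $S_i$,
the heavy metal pollution index is the standard-weighted mean of sub-indices

$$\mathrm{HPI} = \frac{\sum_i W_i Q_i}{\sum_i W_i}, \qquad
  Q_i = 100\,\frac{C_i}{S_i}, \qquad W_i = \frac{1}{S_i},$$

and the metal index is $\mathrm{MI} = \sum_i C_i/\mathrm{UAL}_i$ with the
upper allowable limit equal to the same standard. Both are linear in the
concentration vector, which the test suite exploits: the index of a survey's
mean concentrations equals the mean of its per-sample indices to machine
precision.

The published HPI scale has a gap between its "excellent" (<25) and "good"
(26–50) labels; we resolve it with half-open bins $[0,25)$, $[25,50)$,
$[50,75)$, $[75,100)$, $[100,\infty)$ so that classification is total and
monotone. MI uses half-open bins at cuts 0.3, 1, 2, 4, 6. MI is reported
per sample (the survey's min/max/mean per-sample values are what a
classification table summarizes); `mi_survey_mean()` exposes the
average-concentration variant, which by linearity equals the mean per-sample
MI.

## Deterministic exposure and risk

The exposure model is the USEPA two-route drinking-water model:

$$\mathrm{CDI_{oral}} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT},
\qquad
\mathrm{CDI_{dermal}} = \frac{C \cdot ET \cdot EF \cdot K_p \cdot SA \cdot
CF \cdot ED}{BW \cdot AT},$$

in mg/kg/day, with $\mathrm{HQ} = \mathrm{CDI}/\mathrm{RfD}$ (route-matched
reference dose, $\mathrm{RfD_{dermal}} = \mathrm{RfD_{oral}} \times
\mathrm{ABS}$), $\mathrm{HI} = \sum \mathrm{HQ}$, and for the carcinogens
Cd, Cr, Pb, $\mathrm{CR} = \mathrm{CDI} \times \mathrm{CSF}$. Decision
rules are strict: $\mathrm{HI} > 1$ and $\mathrm{CR} > 10^{-4}$ flag high
risk; the boundary values themselves are low-risk/acceptable.

Parameter choices that deserve comment:

* **Averaging time.** AT = ED × 365 for both receptors and both endpoints
  (adult 25,550 d over ED 70 y; child 2,190 d over ED 6 y). The common
  alternative — a fixed 70-year AT for carcinogenic risk regardless of
  receptor — is deliberately *not* used: child carcinogenic risks here are
  exposure-duration-normalized like the non-carcinogenic ones, and the
  package's reproduced reference values only back-compute under the shared
  AT.
* **Dermal slope factors.** CSF_dermal = 1000 × CSF_oral for Cd, Cr, Pb,
  i.e. the conventional gastrointestinal-absorption adjustment
  CSF_oral/0.001. No independent provenance exists for these dermal values;
  the factor is adopted for numerical consistency with the oral set and is
  flagged here as an inference.
* **Exposure frequency.** EF = 350 day/year for both receptors.
* **Standards.** The default Cu standard is 3 mg/L (not the WHO 2 mg/L);
  all standards are data, not code — override them via the `standards`
  arguments or a YAML parameter file (`write_parameters()` /
  `read_parameters()`, which refuses files whose unit declarations differ
  from the documented ones).
* **Non-carcinogens.** Metals without a slope factor get *no* CR value
  (not zero): requesting one is an error, and tabulated output carries `NA`.

Useful fixed ratios fall out of the model and serve as cross-checks: the
child/adult oral HQ ratio is $(1.8/2.2)\times(70/15) \approx 3.818$ for
every metal and concentration, and dermal HQ computed against RfD_dermal
equals dermal HQ computed against RfD_oral × ABS exactly.

## Monte Carlo risk

`simulate_risk()` propagates concentration uncertainty through the same
equations. Because both CDI equations are linear in concentration, a risk
distribution is the concentration distribution times a deterministic unit
factor; the engine nevertheless simulates (10,000 iterations by default,
matching common practice) so that exceedance fractions, percentile bands
and future non-linear extensions share one code path. Summaries report the
mean, the 5th/50th/95th percentiles (linear interpolation between order
statistics, `stats::quantile` type 7 — stated so results are reproducible
across implementations) and the fraction of draws beyond the decision
threshold.

The concentration law is a **truncated lognormal** by default: survey
analytes are strictly positive, right-skewed, and published with min/max
bounds that a sampling model should respect. `fit_distribution()`
moment-matches the *untruncated* law in closed form
($\sigma^2 = \ln(1 + (sd/mean)^2)$, $\mu = \ln(mean) - \sigma^2/2$) and
truncates afterwards; `match = "truncated"` refines $(\mu, \sigma)$
numerically so the truncated law itself reproduces the target moments
(Nelder–Mead on relative moment errors with a small ridge toward the
closed-form start — pure truncated moment matching is unidentified for very
heavy-tailed analytes, where far-tail parameter pairs reproduce the same
two moments). Truncated normal and uniform families support sensitivity
analysis; `sd = 0` degenerates to a point mass, under which every draw
equals the deterministic risk — a property the tests assert. Exposure
constants are fixed at their tabulated values; only concentration is
treated as uncertain in the default analysis.

Reproducibility contract: one generator, seeded once per `simulate_risk()`
call, metals drawn in the order supplied — identical inputs give
bit-identical summaries. `convergence_report()` re-runs the engine over an
iteration grid and replicate seeds to demonstrate percentile stabilization.

The published probabilistic percentile values for this kind of study cannot
be recomputed from summary statistics alone when the study's sampling
distribution is unstated; the package therefore validates its Monte Carlo
engine against analytic truncated-distribution moments (quadrature oracle,
three-standard-error agreement) rather than against any published
percentile table.

## Synthetic survey generator

No raw survey accompanies the summary statistics the package emulates
(n = 133: 113 carbonate-aquifer wells, 8 springs, 12 lake/drain samples),
so `generate_survey()` produces surveys that reproduce what *is*
published:

1. **Marginals.** Truncated lognormal per analyte, refined so the
   truncated law matches the published mean/sd and clipped to the published
   [min, max]. pH and HCO3 use truncated normals (narrow, symmetric printed
   spreads). CO3 is lognormal despite its printed mean of 6.2 mg/L sitting
   near the zero bound: its coefficient of variation (≈1.4) is infeasible
   for any truncated normal on [0, 35.3], so a near-normal CO3 cannot
   reproduce the published moments.
2. **Dependence.** A Gaussian copula. The published correlations are
   Pearson correlations, so latent correlations are calibrated numerically
   (deterministic stratified quadrature plus 1-D root finding, memoized)
   until the back-transformed Pearson correlation matches the published
   value. Unpublished entries cannot default to zero — with r(Na,Cl) = 0.97
   and r(Na,SO4) = 0.92 published, a zero r(Cl,SO4) is far outside the
   space of valid correlation matrices, and a blunt positive-definite
   repair would then corrupt the published entries. The ion block is
   completed from the published TDS correlations treated as one-factor
   loadings (TDS is the ions' common salinity factor); the metal block by a
   one-factor least-squares fit to its published pairs; a final
   `Matrix::nearPD` projection then only has small inconsistencies to
   absorb.
3. **Salinity structure.** TDS is never sampled — it is the sum of the
   generated ions, consistent with TDS-by-summation, and its published
   statistics are validation targets. The 12 lake/drain rows take the top
   12/133 stratum of each ion's copula score and the remaining rows the
   complementary stratum: the mixture restores each marginal law exactly
   while making the lake/drain group the hypersaline upper tail. Hypersaline
   samples (TDS ≥ 100,000 mg/L) are therefore present with high probability
   but not certainty at n = 133; tests pin this at fixed seeds.
4. **Charge balance.** Samples out of ionic balance (|IBE| > 5%) are
   repaired through chloride first — the dominant counter-ion of these
   brines — within its published bounds, then the minor anions, then the
   cations; only an (empirically unobserved) last resort lets bounds yield
   to the balance rule. Balancing through Cl rather than rescaling all
   anions uniformly keeps the SO4/HCO3/CO3 marginals intact.
5. **Determinism.** Identical configurations and seeds give bit-identical
   surveys.

What the generator does *not* emulate: spatial coordinates and kriging
structure, seasonal replicates, inter-block ion–metal correlations (none
are published), and analytical error. Passing tests on generated surveys
therefore demonstrate the pipeline's correctness and the published-moment
structure, not fidelity to the unpublished raw data: per-survey index
ranges and exact class percentages of the original samples are declared
non-reproducible, and the suite instead asserts the qualitative report
(all samples HPI-unsuitable, ≈100% MI-severely-affected) plus the
linearity, oracle-equivalence and moment-recovery properties.

## Hydrochemical classification

Supporting water-origin quantities use the meq/L basis (mg/L divided by
equivalent weights Na 22.99, K 39.10, Ca 20.04, Mg 12.155, Cl 35.45,
SO4 48.03, HCO3 61.02, CO3 30.005):

* **IBE** = 100 (Σcations − Σanions)/(Σcations + Σanions); |IBE| ≤ 5% is
  the analytical acceptance rule.
* **CAI-I** = [Cl − (Na + K)]/Cl (Schoeller); positive values indicate
  reverse ion exchange. The companion CAI-II is not implemented — it is
  never used numerically in the workflows this package supports.
* **Salinity**: fresh < 1,000, brackish < 10,000, saline < 100,000,
  hypersaline ≥ 100,000 mg/L TDS — the conventional cuts, adopted because
  the emulated study labels its own extremes consistently with them.
* **Sulin genetic types** from equivalence ratios: Na/Cl > 1 splits
  Na2SO4 vs NaHCO3 at (Na−Cl)/SO4 = 1, Na/Cl ≤ 1 splits MgCl2 (recent
  marine) vs CaCl2 (old marine) at (Cl−Na)/Mg = 1. The threshold rules are
  a reconstruction of the classical graphical method; boundaries fall
  deterministically on the CaCl2/NaHCO3 side. Whether ratios are taken on
  raw meq or meq-percent does not change the assignment, since the rules
  are scale-free.

## Numerical choices and degenerate inputs

* Tolerances: HPI/MI linearity holds to 1e-9 relative (tested), the
  vectorized risk path equals a scalar loop to 1e-12 relative, parameter
  identities (RfD route extrapolation, AT = ED × 365) are validated on
  load at 1e-6 relative or better.
* Division guards: Cl = 0 makes CAI-I and Sulin typing undefined-by-error;
  both cation and anion sums zero makes IBE an error; a missing analyte is
  an error naming it, never an imputed zero.
* A zero-concentration analyte still contributes its 1/S weight to the HPI
  denominator — exact formula behaviour, no silent dropping.
* Problem sizes used by the shipped tests: surveys of 133 samples across up
  to 20 seeds for generator-recovery properties, 100 random surveys for the
  linearity suite, 10,000 Monte Carlo iterations for engine validation —
  the scales at which the emulated study conditions are defined.

## Known limitations

* The inhalation route and age-interpolated receptors are out of scope.
* Per-metal CR classes follow the per-metal convention; ΣCR across metals
  is exposed as a column but not classified.
* The generator treats exposure constants as fixed; distributions on
  IR/BW/ED would require the extended configuration left for future work.
* Published whole-survey figures that depend on the unpublished raw data
  (index ranges, class percentages, probabilistic percentile tables) are
  emulated qualitatively, not reproduced numerically.
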