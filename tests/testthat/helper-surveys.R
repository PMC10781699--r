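# Shared fixtures, built in code.

# survey-mean metal concentrations (mg/L) of the emulated study
study_mean_conc <- c(Cd = 0.04, Cr = 0.6, Cu = 1.14, Fe = 2.16,
                     Mn = 0.28, Ni = 0.1, Pb = 0.33, Zn = 0.03)

toy_ion_row <- c(Na = 500, K = 10, Ca = 100, Mg = 60,
                 SO4 = 300, HCO3 = 150, CO3 = 5)

# a small hand-built survey with exact charge balance is not needed; this one
# just satisfies the schema and stays within plausible ranges
make_toy_survey <- function(n = 3) {
  set.seed(99)
  df <- data.frame(
    sample_id = sprintf("T%02d", seq_len(n)),
    source_class = rep(c("TCA_well", "spring", "lake_drain"), length.out = n),
    pH = runif(n, 7, 8.5),
    stringsAsFactors = FALSE
  )
  for (v in names(toy_ion_row)) df[[v]] <- toy_ion_row[[v]] * runif(n, 0.5, 2)
  df$Cl <- 900 * runif(n, 0.5, 2)
  for (m in metal_names()) df[[m]] <- study_mean_conc[[m]] * runif(n, 0.2, 3)
  as_survey(df)
}

# random surveys for property tests: independent positive concentrations,
# no copula structure -- deliberately different from the package generator
random_survey <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    sample_id = sprintf("R%03d", seq_len(n)),
    source_class = sample(c("TCA_well", "spring", "lake_drain"), n,
                          replace = TRUE),
    pH = runif(n, 6.8, 8.7),
    stringsAsFactors = FALSE
  )
  for (v in ion_names()) df[[v]] <- rlnorm(n, log(100), 1)
  for (m in metal_names()) df[[m]] <- rlnorm(n, log(0.1), 1.5)
  as_survey(df)
}

# unit-concentration deterministic risk factor, written out long-hand as an
# independent oracle for the package's vectorized path
oracle_unit_risk <- function(metal, receptor, route, endpoint) {
  tox <- default_metal_toxicity()
  i <- match(metal, tox$metal)
  ex <- default_exposure_profiles()
  p <- ex[ex$receptor == receptor, ]
  cdi <- if (route == "oral") {
    p$ir * p$ef * p$ed / (p$bw * p$at)
  } else {
    p$et * p$ef * tox$kp[i] * p$sa * p$cf * p$ed / (p$bw * p$at)
  }
  if (endpoint == "HQ") {
    rfd <- if (route == "oral") tox$rfd_oral[i] else tox$rfd_dermal[i]
    cdi / rfd
  } else {
    csf <- if (route == "oral") tox$csf_oral[i] else tox$csf_dermal[i]
    cdi * csf
  }
}
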