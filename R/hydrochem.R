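# Hydrochemical derived quantities: meq conversion, TDS by summation, ionic
# balance error, chloro-alkaline index, salinity and Sulin genetic typing.

# equivalent weights (g/eq): concentration mg/L / eq. weight = meq/L
aq_eq_weights <- c(Na = 22.99, K = 39.10, Ca = 20.04, Mg = 12.155,
                   Cl = 35.45, SO4 = 48.03, HCO3 = 61.02, CO3 = 30.005)

#' Convert major-ion concentrations to milliequivalents per litre
#'
#' Divides each ion (mg/L) by its equivalent weight: Na 22.99, K 39.10,
#' Ca 20.04, Mg 12.155, Cl 35.45, SO4 48.03, HCO3 61.02, CO3 30.005 g/eq.
#'
#' @param x A `water_survey`, data.frame with ion columns, or named vector.
#' @return A matrix (n x 8) of meq/L values.
#' @export
to_meq <- function(x) {
  m <- ion_matrix(x)
  sweep(m, 2, aq_eq_weights[colnames(m)], "/")
}

#' Total dissolved solids by ion summation
#'
#' TDS (mg/L) computed as the sum of the eight major-ion concentrations.
#'
#' @param x A `water_survey`, data.frame or named ion vector.
#' @return Numeric vector of TDS values, mg/L.
#' @export
tds_by_summation <- function(x) {
  rowSums(ion_matrix(x))
}

#' Ionic balance error
#'
#' IBE (%) = 100 x (sum cations - sum anions) / (sum cations + sum anions)
#' on the meq/L basis. |IBE| <= 5% is the conventional analytical acceptance
#' rule.
#'
#' @param x A `water_survey`, data.frame or named ion vector.
#' @return Numeric vector of IBE percentages.
#' @export
ionic_balance_error <- function(x) {
  meq <- to_meq(x)
  cat_sum <- rowSums(meq[, aq_cations, drop = FALSE])
  an_sum  <- rowSums(meq[, aq_anions, drop = FALSE])
  tot <- cat_sum + an_sum
  if (any(tot == 0))
    stop("undefined ionic balance: cation and anion sums are both zero in row(s) ",
         paste(which(tot == 0), collapse = ", "))
  unname(100 * (cat_sum - an_sum) / tot)
}

#' Chloro-alkaline index CAI-I
#'
#' CAI-I = (Cl - (Na + K)) / Cl on the meq/L basis. A positive value
#' indicates reverse ion exchange (water Na+/K+ exchanged for rock
#' Ca2+/Mg2+); a negative value indicates direct ion exchange. The index is
#' invariant under uniform scaling of all ion concentrations.
#'
#' @param x A `water_survey`, data.frame or named ion vector.
#' @return Numeric vector of CAI-I values (dimensionless).
#' @export
cai_one <- function(x) {
  meq <- to_meq(x)
  cl <- meq[, "Cl"]
  if (any(cl == 0))
    stop("undefined chloro-alkaline index: Cl is zero in row(s) ",
         paste(which(cl == 0), collapse = ", "))
  unname((cl - (meq[, "Na"] + meq[, "K"])) / cl)
}

#' Classify water salinity from TDS
#'
#' Conventional cuts (mg/L): fresh < 1,000; brackish 1,000 to <10,000;
#' saline 10,000 to <100,000; hypersaline >= 100,000.
#'
#' @param tds Numeric vector of TDS values (mg/L), non-negative.
#' @return Character vector of classes.
#' @export
classify_salinity <- function(tds) {
  if (any(!is.finite(tds)) || any(tds < 0))
    stop("tds must be finite and non-negative")
  cut(tds, breaks = c(-Inf, 1000, 10000, 100000, Inf), right = FALSE,
      labels = c("fresh", "brackish", "saline", "hypersaline")) |>
    as.character()
}

#' Sulin genetic water type
#'
#' Assigns each sample one of the four Sulin genetic types from the
#' meq-basis genetic coefficients: with rNa = Na meq and rCl = Cl meq,
#' if Na/Cl > 1 the water is meteoric-family — Na2SO4 type when
#' (Na - Cl)/SO4 < 1, else NaHCO3; if Na/Cl <= 1 the water is marine-family —
#' MgCl2 (recent marine) when (Cl - Na)/Mg < 1, else CaCl2 (old marine).
#' Boundaries (ratios exactly 1) fall deterministically on the CaCl2 /
#' NaHCO3 side.
#'
#' @param x A `water_survey`, data.frame or named ion vector.
#' @return Character vector of types: `MgCl2`, `CaCl2`, `Na2SO4`, `NaHCO3`.
#' @export
sulin_type <- function(x) {
  meq <- to_meq(x)
  na <- meq[, "Na"]; cl <- meq[, "Cl"]
  mg <- meq[, "Mg"]; so4 <- meq[, "SO4"]
  if (any(cl == 0))
    stop("undefined Sulin type: Cl is zero in row(s) ",
         paste(which(cl == 0), collapse = ", "))
  out <- character(length(na))
  up <- na / cl > 1
  if (any(up)) {
    if (any(so4[up] == 0))
      stop("undefined Sulin type: SO4 is zero where Na/Cl > 1 (row(s) ",
           paste(which(up & so4 == 0), collapse = ", "), ")")
    out[up] <- ifelse((na[up] - cl[up]) / so4[up] < 1, "Na2SO4", "NaHCO3")
  }
  if (any(!up)) {
    if (any(mg[!up] == 0))
      stop("undefined Sulin type: Mg is zero where Na/Cl <= 1 (row(s) ",
           paste(which(!up & mg == 0), collapse = ", "), ")")
    out[!up] <- ifelse((cl[!up] - na[!up]) / mg[!up] < 1, "MgCl2", "CaCl2")
  }
  out
}

#' Hydrochemical summary of a survey
#'
#' Appends to the survey the derived columns `TDS_sum`, `IBE_pct`, `CAI_I`,
#' `salinity_class` and `sulin_type`.
#'
#' @param survey A `water_survey`.
#' @return A data.frame: the survey columns plus the five derived columns.
#' @export
hydrochem_summary <- function(survey) {
  survey <- as_survey(survey, attr(survey, "provenance") %||% "in-memory")
  out <- as.data.frame(survey)
  out$TDS_sum <- tds_by_summation(survey)
  out$IBE_pct <- ionic_balance_error(survey)
  out$CAI_I <- cai_one(survey)
  out$salinity_class <- classify_salinity(out$TDS_sum)
  out$sulin_type <- sulin_type(survey)
  out
}
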