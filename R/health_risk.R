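# Deterministic USEPA-style exposure and risk:
#   CDI_oral   = C * IR * EF * ED / (BW * AT)
#   CDI_dermal = C * ET * EF * Kp * SA * CF * ED / (BW * AT)
#   HQ = CDI / RfD (route-matched RfD), HI = sum(HQ), CR = CDI * CSF.
# The same averaging time AT = ED * 365 is used for non-carcinogenic and
# carcinogenic endpoints for both receptors.

check_profile <- function(profile) {
  need <- c("ir", "ef", "ed", "bw", "at", "sa", "et", "cf")
  if (is.character(profile))
    profile <- exposure_profile(load_default_parameters(), profile)
  if (!all(need %in% names(profile)))
    stop("exposure profile must carry fields: ", paste(need, collapse = ", "))
  as.list(profile[1, need])
}

#' Chronic daily intake, oral route
#'
#' CDI_oral (mg/kg/day) = C x IR x EF x ED / (BW x AT) for concentration C
#' (mg/L).
#'
#' @param conc Concentration(s), mg/L, non-negative.
#' @param profile An exposure profile: a row of
#'   [default_exposure_profiles()], or `"adult"`/`"child"` for the defaults.
#' @return Numeric vector of doses, mg/kg/day.
#' @export
#' @examples
#' cdi_oral(1, "adult")  # 2.2*350*70/(70*25550) = 0.0301370
cdi_oral <- function(conc, profile) {
  p <- check_profile(profile)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  conc * p$ir * p$ef * p$ed / (p$bw * p$at)
}

#' Chronic daily intake, dermal route
#'
#' CDI_dermal (mg/kg/day) = C x ET x EF x Kp x SA x CF x ED / (BW x AT).
#'
#' @inheritParams cdi_oral
#' @param kp Dermal permeability coefficient, cm/h, positive.
#' @return Numeric vector of absorbed doses, mg/kg/day.
#' @export
cdi_dermal <- function(conc, profile, kp) {
  p <- check_profile(profile)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("kp must be finite and positive")
  conc * p$et * p$ef * kp * p$sa * p$cf * p$ed / (p$bw * p$at)
}

#' Hazard quotient
#'
#' HQ = CDI / RfD with the route-matched reference dose (oral RfD for oral
#' CDI; dermal RfD = oral RfD x ABS for dermal CDI).
#'
#' @param cdi Chronic daily intake, mg/kg/day.
#' @param rfd Reference dose, mg/kg/day, positive.
#' @return Dimensionless hazard quotient(s).
#' @export
hq <- function(cdi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0))
    stop("invalid parameter: rfd must be finite and positive")
  cdi / rfd
}

#' Hazard index
#'
#' Arithmetic sum of the per-metal hazard quotients of one receptor and one
#' exposure route.
#'
#' @param hqs Numeric vector (one HQ per metal) or matrix (samples x metals).
#' @return The summed hazard index (per sample for a matrix).
#' @export
hi <- function(hqs) {
  if (is.matrix(hqs)) return(rowSums(hqs))
  sum(hqs)
}

#' Carcinogenic risk
#'
#' CR = CDI x CSF, the incremental lifetime cancer probability.
#'
#' @param cdi Chronic daily intake, mg/kg/day.
#' @param csf Cancer slope factor, (mg/kg/day)^-1, non-negative. `NA` (a
#'   metal without a slope factor) is an error: risk is not applicable, not
#'   zero.
#' @return Dimensionless risk(s).
#' @export
cr <- function(cdi, csf) {
  if (any(is.na(csf)))
    stop("carcinogenic risk is not applicable: no cancer slope factor for this metal")
  if (any(!is.finite(csf)) || any(csf < 0))
    stop("csf must be finite and non-negative")
  cdi * csf
}

#' Classify a hazard index
#'
#' `high_risk` iff HI > 1 (strict), else `low_risk`.
#'
#' @param x Numeric vector of HI values, non-negative.
#' @return Character vector.
#' @export
classify_hi <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("hi must be finite and non-negative")
  ifelse(x > 1, "high_risk", "low_risk")
}

#' Classify a carcinogenic risk
#'
#' `high_risk` iff CR > 1e-4 (strict), else `acceptable`.
#'
#' @param x Numeric vector of CR values, non-negative.
#' @return Character vector.
#' @export
classify_cr <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("cr must be finite and non-negative")
  ifelse(x > 1e-4, "high_risk", "acceptable")
}

#' Full deterministic risk table for a survey
#'
#' Computes, for every sample x receptor x route, the per-metal CDI, HQ and
#' (for Cd, Cr, Pb) CR; the per-route hazard index HI with its class; and a
#' classification summary in the conventional report layout.
#'
#' @param survey A `water_survey`.
#' @param params A `risk_parameters` object (default package constants).
#' @param receptors Receptors to assess (default both).
#' @param routes Exposure routes to assess (default both).
#' @return A list with data.frames `by_metal` (sample_id, receptor, route,
#'   metal, conc, cdi, hq, cr, cr_class), `hi` (sample_id, receptor, route,
#'   hi, hi_class, total_cr) and `summary`.
#' @export
risk_table <- function(survey, params = load_default_parameters(),
                       receptors = c("adult", "child"),
                       routes = c("oral", "dermal")) {
  survey <- as_survey(survey, attr(survey, "provenance") %||% "in-memory")
  validate_parameters(params)
  receptors <- match.arg(receptors, c("adult", "child"), several.ok = TRUE)
  routes <- match.arg(routes, c("oral", "dermal"), several.ok = TRUE)
  conc <- metal_matrix(survey)
  tox <- params$toxicity
  tox <- tox[match(aq_metals, tox$metal), ]
  n <- nrow(conc)
  by_metal <- list(); hi_rows <- list()
  for (rec in receptors) {
    prof <- params$exposure[params$exposure$receptor == rec, , drop = FALSE]
    for (route in routes) {
      if (route == "oral") {
        cdi_m <- cdi_oral(conc, prof)               # element-wise on matrix
        rfd <- tox$rfd_oral; csf <- tox$csf_oral
      } else {
        unit <- cdi_dermal(1, prof, tox$kp)         # per-metal unit dose
        cdi_m <- conc * rep(unit, each = n)
        rfd <- tox$rfd_dermal; csf <- tox$csf_dermal
      }
      hq_m <- sweep(cdi_m, 2, rfd, "/")
      cr_m <- sweep(cdi_m, 2, csf, "*")             # NA where no CSF
      hi_v <- hi(hq_m)
      crv <- as.vector(cr_m)
      cr_cl <- rep(NA_character_, length(crv))
      cr_cl[!is.na(crv)] <- classify_cr(crv[!is.na(crv)])
      by_metal[[paste(rec, route)]] <- data.frame(
        sample_id = rep(survey$sample_id, times = length(aq_metals)),
        receptor = rec, route = route,
        metal = rep(aq_metals, each = n),
        conc = as.vector(conc),
        cdi = as.vector(cdi_m),
        hq = as.vector(hq_m),
        cr = crv,
        cr_class = cr_cl,
        stringsAsFactors = FALSE
      )
      hi_rows[[paste(rec, route)]] <- data.frame(
        sample_id = survey$sample_id, receptor = rec, route = route,
        hi = hi_v, hi_class = classify_hi(hi_v),
        total_cr = rowSums(cr_m, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  by_metal <- do.call(rbind, c(by_metal, make.row.names = FALSE))
  hi_df <- do.call(rbind, c(hi_rows, make.row.names = FALSE))
  list(by_metal = by_metal, hi = hi_df,
       summary = summarize_risk(by_metal, hi_df))
}

cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))

hi_bins <- function() data.frame(
  range = c("< 1", "> 1"), class = c("low_risk", "high_risk"),
  stringsAsFactors = FALSE)

cr_bins <- function() data.frame(
  range = c("< 1e-04", "> 1e-04"), class = c("acceptable", "high_risk"),
  stringsAsFactors = FALSE)

#' Classification summary of deterministic risk results
#'
#' One block per HI receptor/route combination and one per carcinogenic
#' metal/receptor/route combination, each with min/max/mean and per-class
#' sample counts and percentages.
#'
#' @param by_metal,hi_df The data.frames produced by [risk_table()].
#' @return A summary data.frame.
#' @export
summarize_risk <- function(by_metal, hi_df) {
  blocks <- list()
  for (rec in unique(hi_df$receptor)) {
    for (route in unique(hi_df$route)) {
      sub <- hi_df[hi_df$receptor == rec & hi_df$route == route, ]
      if (!nrow(sub)) next
      lab <- sprintf("HI %s (%s)", cap(rec), cap(route))
      blocks[[lab]] <- class_summary_rows(lab, sub$hi, sub$hi_class, hi_bins())
    }
  }
  carc <- by_metal[!is.na(by_metal$cr), ]
  for (metal in intersect(aq_carcinogens, unique(carc$metal))) {
    for (rec in unique(carc$receptor)) {
      for (route in unique(carc$route)) {
        sub <- carc[carc$metal == metal & carc$receptor == rec &
                      carc$route == route, ]
        if (!nrow(sub)) next
        lab <- sprintf("CR%s %s (%s)", metal, cap(rec), cap(route))
        blocks[[lab]] <- class_summary_rows(lab, sub$cr, sub$cr_class,
                                            cr_bins())
      }
    }
  }
  do.call(rbind, c(blocks, make.row.names = FALSE))
}
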