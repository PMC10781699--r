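# Reference constants for the exposure model. All concentration inputs are
# mg/L; doses are mg per kg body weight per day.

#' Canonical analyte names
#'
#' Fixed column orderings used throughout the package: the eight heavy metals,
#' the eight major ions, and their split into cations and anions.
#'
#' @name analytes
#' @keywords internal
NULL

aq_metals  <- c("Cd", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn")
aq_ions    <- c("Na", "K", "Ca", "Mg", "Cl", "SO4", "HCO3", "CO3")
aq_cations <- c("Na", "K", "Ca", "Mg")
aq_anions  <- c("Cl", "SO4", "HCO3", "CO3")
aq_carcinogens <- c("Cd", "Cr", "Pb")

#' Metal names handled by the package
#'
#' @return Character vector of the eight heavy metals, in canonical order.
#' @export
metal_names <- function() aq_metals

#' Major-ion names handled by the package
#'
#' @return Character vector of the eight major ions, in canonical order.
#' @export
ion_names <- function() aq_ions

#' Default per-metal toxicity and standards table
#'
#' Reference data for the eight metals: oral reference dose (RfD, mg/kg/day),
#' gastrointestinal absorption fraction (ABS), dermal reference dose
#' (RfD_dermal = RfD_oral x ABS), oral and dermal cancer slope factors (CSF,
#' (mg/kg/day)^-1; only Cd, Cr and Pb are treated as carcinogens, others are
#' `NA`), dermal permeability coefficient Kp (cm/h), and the drinking-water
#' standard Si (mg/L) used both as the HPI standard and as the MI upper
#' allowable limit. The dermal slope factors follow the conventional
#' CSF_dermal = CSF_oral / 0.001 gastrointestinal adjustment, i.e. a fixed
#' factor of 1000 above the oral value.
#'
#' Note the Cu standard is 3 mg/L here (not the WHO 2 mg/L); all standards are
#' overridable via the `standards` arguments of downstream functions or a
#' parameter config file.
#'
#' @return A data.frame with one row per metal.
#' @export
#' @examples
#' tox <- default_metal_toxicity()
#' stopifnot(all(abs(tox$rfd_dermal - tox$rfd_oral * tox$abs_gi) < 1e-12))
default_metal_toxicity <- function() {
  rfd_oral <- c(0.0005, 0.003, 0.04, 0.7, 0.024, 0.02, 0.0014, 0.3)
  abs_gi   <- c(0.05, 0.025, 0.3, 0.2, 0.04, 0.04, 0.3, 0.2)
  data.frame(
    metal      = aq_metals,
    rfd_oral   = rfd_oral,
    abs_gi     = abs_gi,
    rfd_dermal = rfd_oral * abs_gi,
    csf_oral   = c(6.1, 0.5, NA, NA, NA, NA, 0.5, NA),
    csf_dermal = c(6100, 500, NA, NA, NA, NA, 500, NA),
    kp         = c(0.001, 0.002, 0.001, 0.001, 0.001, 0.0002, 0.0001, 0.0006),
    standard_si = c(0.003, 0.05, 3, 0.3, 0.05, 0.07, 0.01, 1),
    stringsAsFactors = FALSE
  )
}

#' Default receptor exposure profiles
#'
#' Exposure constants for the adult and child receptors: ingestion rate IR
#' (L/day), exposure frequency EF (day/year), exposure duration ED (year),
#' body weight BW (kg), averaging time AT (day, = ED x 365 for both
#' receptors and both endpoints), exposed skin area SA (cm2), exposure time
#' ET (h/day) and the volumetric conversion factor CF (L/cm3).
#'
#' @return A data.frame with rows `adult` and `child`.
#' @export
default_exposure_profiles <- function() {
  data.frame(
    receptor = c("adult", "child"),
    ir = c(2.2, 1.8),
    ef = c(350, 350),
    ed = c(70, 6),
    bw = c(70, 15),
    at = c(25550, 2190),
    sa = c(18000, 6600),
    et = c(0.58, 1),
    cf = c(0.001, 0.001),
    stringsAsFactors = FALSE
  )
}

#' Load the full default parameter set
#'
#' @return An object of class `risk_parameters`: a list with elements
#'   `toxicity` (see [default_metal_toxicity()]) and `exposure`
#'   (see [default_exposure_profiles()]).
#' @export
load_default_parameters <- function() {
  params <- list(
    toxicity = default_metal_toxicity(),
    exposure = default_exposure_profiles()
  )
  class(params) <- "risk_parameters"
  validate_parameters(params)
  params
}

#' Validate a risk-parameter set
#'
#' Checks structure, positivity, the RfD_dermal = RfD_oral x ABS identity and
#' the AT = ED x 365 averaging-time identity. Called on load and after reading
#' a config file.
#'
#' @param params A `risk_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_parameters <- function(params) {
  if (!is.list(params) || !all(c("toxicity", "exposure") %in% names(params)))
    stop("parameters must be a list with elements 'toxicity' and 'exposure'")
  tox <- params$toxicity
  need <- c("metal", "rfd_oral", "abs_gi", "rfd_dermal", "csf_oral",
            "csf_dermal", "kp", "standard_si")
  miss <- setdiff(need, names(tox))
  if (length(miss))
    stop("toxicity table is missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(tox$metal, aq_metals))
    stop("toxicity table must contain exactly the metals ",
         paste(aq_metals, collapse = ", "))
  num <- tox[c("rfd_oral", "abs_gi", "rfd_dermal", "kp", "standard_si")]
  if (!all(vapply(num, function(x) all(is.finite(x) & x > 0), logical(1))))
    stop("rfd_oral, abs_gi, rfd_dermal, kp and standard_si must all be finite and positive")
  if (any(tox$abs_gi > 1))
    stop("abs_gi must be a fraction in (0, 1]")
  rel <- abs(tox$rfd_dermal - tox$rfd_oral * tox$abs_gi) /
    (tox$rfd_oral * tox$abs_gi)
  if (any(rel > 1e-6))
    stop("rfd_dermal must equal rfd_oral * abs_gi (route-consistency identity) ",
         "for every metal; violated for: ",
         paste(tox$metal[rel > 1e-6], collapse = ", "))
  has_csf <- tox$metal[!is.na(tox$csf_oral)]
  if (!setequal(has_csf, aq_carcinogens) ||
      !setequal(tox$metal[!is.na(tox$csf_dermal)], aq_carcinogens))
    stop("csf_oral and csf_dermal must be present for exactly Cd, Cr, Pb")
  exp <- params$exposure
  needx <- c("receptor", "ir", "ef", "ed", "bw", "at", "sa", "et", "cf")
  missx <- setdiff(needx, names(exp))
  if (length(missx))
    stop("exposure table is missing column(s): ", paste(missx, collapse = ", "))
  if (!setequal(exp$receptor, c("adult", "child")))
    stop("exposure table must contain exactly receptors 'adult' and 'child'")
  numx <- exp[c("ir", "ef", "ed", "bw", "at", "sa", "et", "cf")]
  if (!all(vapply(numx, function(x) all(is.finite(x) & x > 0), logical(1))))
    stop("all exposure constants must be finite and positive")
  if (any(exp$ef > 365))
    stop("exposure frequency ef must lie in (0, 365] day/year")
  if (any(abs(exp$at - exp$ed * 365) > 1e-9))
    stop("averaging time must satisfy at = ed * 365 for every receptor")
  invisible(params)
}

#' @export
print.risk_parameters <- function(x, ...) {
  cat("Risk parameter set\n")
  cat("Toxicity table (", nrow(x$toxicity), " metals):\n", sep = "")
  print(x$toxicity, row.names = FALSE)
  cat("Exposure profiles:\n")
  print(x$exposure, row.names = FALSE)
  invisible(x)
}

#' Dermal reference dose from the oral reference dose
#'
#' Applies the route-extrapolation identity RfD_dermal = RfD_oral x ABS, where
#' ABS is the gastrointestinal absorption fraction.
#'
#' @param rfd_oral Oral reference dose, mg/kg/day, positive.
#' @param abs_gi Gastrointestinal absorption fraction, positive.
#' @return Dermal reference dose, mg/kg/day.
#' @export
#' @examples
#' derive_rfd_dermal(0.0005, 0.05)  # 2.5e-05 (Cd)
derive_rfd_dermal <- function(rfd_oral, abs_gi) {
  if (!is.numeric(rfd_oral) || !is.numeric(abs_gi))
    stop("rfd_oral and abs_gi must be numeric")
  if (any(!is.finite(rfd_oral)) || any(!is.finite(abs_gi)) ||
      any(rfd_oral <= 0) || any(abs_gi <= 0))
    stop("invalid parameter: rfd_oral and abs_gi must be finite and positive")
  rfd_oral * abs_gi
}

#' Retrieve one receptor's exposure profile
#'
#' @param params A `risk_parameters` object.
#' @param receptor `"adult"` or `"child"`.
#' @return A one-row data.frame of exposure constants.
#' @export
exposure_profile <- function(params = load_default_parameters(),
                             receptor = c("adult", "child")) {
  receptor <- match.arg(receptor)
  params$exposure[params$exposure$receptor == receptor, , drop = FALSE]
}

# unit strings written alongside the config so files are self-describing
aq_param_units <- list(
  rfd_oral = "mg/kg/day", abs_gi = "fraction", rfd_dermal = "mg/kg/day",
  csf_oral = "(mg/kg/day)^-1", csf_dermal = "(mg/kg/day)^-1", kp = "cm/h",
  standard_si = "mg/L", ir = "L/day", ef = "day/year", ed = "year",
  bw = "kg", at = "day", sa = "cm2", et = "h/day", cf = "L/cm3"
)

#' Write a parameter set to a YAML config file
#'
#' The file maps each metal and receptor to its constants and carries a
#' mandatory `units` block so the file is interpretable on its own.
#'
#' @param params A `risk_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  tox <- params$toxicity
  exp <- params$exposure
  as_map <- function(df, key) {
    out <- lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, setdiff(names(df), key)])
      lapply(row, function(v) if (is.na(v)) NULL else v)
    })
    names(out) <- df[[key]]
    out
  }
  doc <- list(
    units = aq_param_units,
    metals = as_map(tox, "metal"),
    receptors = as_map(exp, "receptor")
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a parameter set from a YAML config file
#'
#' Inverse of [write_parameters()]. The file must carry a `units` block whose
#' entries match the package's documented units; this guards against config
#' files written on a different unit convention.
#'
#' @param path Config file path.
#' @return A validated `risk_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$units))
    stop("parameter file lacks the mandatory 'units' block: ", path)
  bad <- names(doc$units)[!vapply(names(doc$units), function(k)
    identical(doc$units[[k]], aq_param_units[[k]]), logical(1))]
  if (length(bad))
    stop("unit mismatch in parameter file for: ", paste(bad, collapse = ", "))
  from_map <- function(map, key, cols) {
    rows <- lapply(names(map), function(k) {
      row <- map[[k]]
      vals <- lapply(cols, function(cn) {
        v <- row[[cn]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      })
      names(vals) <- cols
      cbind(data.frame(k, stringsAsFactors = FALSE), as.data.frame(vals))
    })
    out <- do.call(rbind, rows)
    names(out)[1] <- key
    out
  }
  tox <- from_map(doc$metals, "metal",
                  c("rfd_oral", "abs_gi", "rfd_dermal", "csf_oral",
                    "csf_dermal", "kp", "standard_si"))
  tox <- tox[match(aq_metals, tox$metal), ]
  rownames(tox) <- NULL
  exp <- from_map(doc$receptors, "receptor",
                  c("ir", "ef", "ed", "bw", "at", "sa", "et", "cf"))
  exp <- exp[match(c("adult", "child"), exp$receptor), ]
  rownames(exp) <- NULL
  params <- structure(list(toxicity = tox, exposure = exp),
                      class = "risk_parameters")
  validate_parameters(params)
  params
}

#' Default drinking-water standards
#'
#' Named vector of the per-metal standard Si (mg/L), used as the HPI standard
#' and as the MI upper allowable limit.
#'
#' @return Named numeric vector over the eight metals.
#' @export
default_standards <- function() {
  tox <- default_metal_toxicity()
  stats::setNames(tox$standard_si, tox$metal)
}
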