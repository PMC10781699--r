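# Heavy metal pollution index (HPI) and metal index (MI) with their
# classification scales and a survey-level summary.
#
# HPI is the standard-weighted mean of sub-indices: Qi = 100 Ci / Si,
# wi = 1 / Si, HPI = sum(wi Qi) / sum(wi). MI = sum(Ci / UALi), where the
# upper allowable limit UAL is the same drinking-water standard Si. Both are
# linear in the concentration vector.

resolve_standards <- function(standards, metals) {
  if (is.null(standards)) standards <- default_standards()
  if (is.null(names(standards)))
    stop("standards must be a named vector (metal -> mg/L)")
  miss <- setdiff(metals, names(standards))
  if (length(miss))
    stop("missing standard(s) for metal(s): ", paste(miss, collapse = ", "))
  s <- standards[metals]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all standards must be finite and positive")
  s
}

#' Heavy metal pollution index
#'
#' @param x Metal concentrations (mg/L): a `water_survey`, a data.frame or
#'   matrix with metal columns, or a named vector for a single sample.
#' @param standards Named vector of standards Si (mg/L); defaults to the
#'   package standards ([default_standards()]). The metal set assessed is the
#'   intersection of the columns of `x` with the canonical eight unless `x`
#'   carries a different named set, in which case every named analyte is used
#'   (a zero-concentration analyte still contributes its 1/Si weight to the
#'   denominator — no silent dropping).
#' @return Numeric vector of HPI values, one per sample.
#' @export
hpi <- function(x, standards = NULL) {
  m <- metal_matrix(x, metals = index_metals(x))
  s <- resolve_standards(standards, colnames(m))
  w <- 1 / s
  qi <- sweep(m, 2, s, "/") * 100
  as.numeric(qi %*% w) / sum(w)
}

#' Metal index
#'
#' MI = sum over metals of concentration / upper allowable limit.
#'
#' @inheritParams hpi
#' @return Numeric vector of MI values, one per sample.
#' @export
mi <- function(x, standards = NULL) {
  m <- metal_matrix(x, metals = index_metals(x))
  s <- resolve_standards(standards, colnames(m))
  as.numeric(m %*% (1 / s))
}

# metal set carried by the input: canonical eight for surveys, the named set
# for explicit vectors/matrices (lets callers assess extended analyte sets)
index_metals <- function(x) {
  if (inherits(x, "water_survey")) return(aq_metals)
  if (is.data.frame(x)) {
    # survey-shaped tables must carry the full canonical metal set
    if (any(c("sample_id", "source_class") %in% names(x))) return(aq_metals)
    return(setdiff(names(x), c("pH", aq_ions)))
  }
  nm <- if (is.matrix(x)) colnames(x) else names(x)
  if (is.null(nm)) stop("concentrations must be named by metal")
  setdiff(nm, c("sample_id", "source_class", "pH", aq_ions))
}

#' Classify an HPI value
#'
#' Half-open bins: [0,25) excellent, [25,50) good, [50,75) poor,
#' [75,100) very poor, [100, Inf) unsuitable (high pollution risk).
#'
#' @param x Numeric vector of HPI values, non-negative.
#' @return Character vector of classes.
#' @export
classify_hpi <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("hpi values must be finite and non-negative")
  as.character(cut(x, breaks = c(-Inf, 25, 50, 75, 100, Inf), right = FALSE,
                   labels = c("excellent", "good", "poor", "very_poor",
                              "unsuitable")))
}

#' Classify an MI value
#'
#' Half-open bins at cuts 0.3, 1, 2, 4, 6: very clean, clean, partly
#' affected, moderately affected, heavily affected, severely affected.
#'
#' @param x Numeric vector of MI values, non-negative.
#' @return Character vector of classes.
#' @export
classify_mi <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("mi values must be finite and non-negative")
  as.character(cut(x, breaks = c(-Inf, 0.3, 1, 2, 4, 6, Inf), right = FALSE,
                   labels = c("very_clean", "clean", "partly_affected",
                              "moderately_affected", "heavily_affected",
                              "severely_affected")))
}

#' Per-sample index breakdown
#'
#' Full decomposition for one sample: per-metal sub-indices Qi and weights
#' wi, HPI, MI and both class labels.
#'
#' @param conc Named vector of metal concentrations (mg/L).
#' @param standards Named vector of standards Si (mg/L); default package set.
#' @return A list with elements `qi`, `wi`, `hpi`, `mi`, `hpi_class`,
#'   `mi_class`.
#' @export
index_breakdown <- function(conc, standards = NULL) {
  m <- metal_matrix(conc, metals = index_metals(conc))
  s <- resolve_standards(standards, colnames(m))
  qi <- 100 * m[1, ] / s
  wi <- 1 / s
  h <- sum(wi * qi) / sum(wi)
  mi_val <- sum(m[1, ] / s)
  list(qi = qi, wi = wi, hpi = h, mi = mi_val,
       hpi_class = classify_hpi(h), mi_class = classify_mi(mi_val))
}

#' Survey-mean metal index
#'
#' MI evaluated at the survey-mean concentration of each metal (the
#' average-concentration reading of the index); by linearity this equals the
#' mean of the per-sample MI values.
#'
#' @param survey A `water_survey`.
#' @param standards Named vector of standards (mg/L).
#' @return A single MI value.
#' @export
mi_survey_mean <- function(survey, standards = NULL) {
  m <- metal_matrix(survey)
  mi(colMeans(m), standards)
}

class_summary_rows <- function(criteria, values, classes, bins) {
  # bins: data.frame(range, class) in display order
  n <- length(values)
  counts <- vapply(bins$class, function(cl) sum(classes == cl), integer(1))
  data.frame(
    criteria = c(criteria, rep("", nrow(bins) - 1)),
    min = c(min(values), rep(NA, nrow(bins) - 1)),
    max = c(max(values), rep(NA, nrow(bins) - 1)),
    mean = c(mean(values), rep(NA, nrow(bins) - 1)),
    range = bins$range,
    class = bins$class,
    n = as.integer(counts),
    pct = 100 * counts / n,
    stringsAsFactors = FALSE
  )
}

hpi_bins <- function() data.frame(
  range = c("< 25", "25-50", "50-75", "75-100", "> 100"),
  class = c("excellent", "good", "poor", "very_poor", "unsuitable"),
  stringsAsFactors = FALSE)

mi_bins <- function() data.frame(
  range = c("MI < 0.3", "0.3 < MI < 1", "1 < MI < 2", "2 < MI < 4",
            "4 < MI < 6", "MI > 6"),
  class = c("very_clean", "clean", "partly_affected", "moderately_affected",
            "heavily_affected", "severely_affected"),
  stringsAsFactors = FALSE)

#' Summarize pollution indices over a survey
#'
#' Per-sample HPI and MI plus a classification summary in the conventional
#' report layout (criteria, min, max, mean, range, class, sample count and
#' percentage per class).
#'
#' @param survey A `water_survey`.
#' @param standards Named vector of standards (mg/L); default package set.
#' @return A list: `per_sample` (data.frame sample_id, hpi, mi and classes)
#'   and `summary` (classification table).
#' @export
summarize_indices <- function(survey, standards = NULL) {
  survey <- as_survey(survey, attr(survey, "provenance") %||% "in-memory")
  h <- hpi(survey, standards)
  m <- mi(survey, standards)
  per_sample <- data.frame(
    sample_id = survey$sample_id,
    hpi = h, hpi_class = classify_hpi(h),
    mi = m, mi_class = classify_mi(m),
    stringsAsFactors = FALSE
  )
  summary <- rbind(
    class_summary_rows("MI", m, per_sample$mi_class, mi_bins()),
    class_summary_rows("HPI", h, per_sample$hpi_class, hpi_bins())
  )
  list(per_sample = per_sample, summary = summary)
}
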