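# Survey data model and CSV I/O.
#
# A survey is a plain data.frame of class "water_survey" with one row per
# sample and the fixed column schema below. All concentrations are mg/L; pH is
# unitless. Missing values are explicit NA (empty cells on disk), never zero.

aq_survey_columns <- function() {
  c("sample_id", "source_class", "pH", aq_ions, aq_metals)
}

aq_source_classes <- c("TCA_well", "spring", "lake_drain")

#' Construct and validate a water survey
#'
#' @param df A data.frame with columns `sample_id`, `source_class`, `pH`, the
#'   eight major ions (Na, K, Ca, Mg, Cl, SO4, HCO3, CO3) and the eight metals
#'   (Cd, Cr, Cu, Fe, Mn, Ni, Pb, Zn), all concentrations in mg/L.
#' @param provenance Free-text provenance note (file path or "synthetic:seed").
#' @return A validated `water_survey` data.frame (columns in schema order;
#'   pass-through columns such as field EC are kept after the schema columns).
#' @export
as_survey <- function(df, provenance = "in-memory") {
  if (!is.data.frame(df)) stop("survey must be a data.frame")
  have <- tolower(names(df))
  want <- aq_survey_columns()
  idx <- match(tolower(want), have)
  if (anyNA(idx)) {
    stop("survey is missing mandatory column(s): ",
         paste(want[is.na(idx)], collapse = ", "))
  }
  extra <- setdiff(seq_along(df), idx)
  df <- df[, c(idx, extra), drop = FALSE]
  names(df)[seq_along(want)] <- want
  if (nrow(df) < 1) stop("survey must contain at least one sample")
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  bad_class <- !df$source_class %in% aq_source_classes
  if (any(bad_class))
    stop("invalid source_class in row(s) ",
         paste(which(bad_class), collapse = ", "),
         " (allowed: ", paste(aq_source_classes, collapse = ", "), ")")
  conc_cols <- c("pH", aq_ions, aq_metals)
  for (cn in conc_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      nonnum <- which(!is.na(v) & v != "" & is.na(v2))
      if (length(nonnum))
        stop("non-numeric value for '", cn, "' in row(s) ",
             paste(nonnum, collapse = ", "))
      v2[!is.na(v) & v == ""] <- NA_real_
      v <- v2
    }
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      stop("negative concentration for '", cn, "' in row(s) ",
           paste(neg, collapse = ", "))
    inf <- which(is.infinite(v))
    if (length(inf))
      stop("non-finite concentration for '", cn, "' in row(s) ",
           paste(inf, collapse = ", "))
    df[[cn]] <- v
  }
  bad_ph <- which(!is.na(df$pH) & (df$pH < 0 | df$pH > 14))
  if (length(bad_ph))
    stop("pH outside [0, 14] in row(s) ", paste(bad_ph, collapse = ", "))
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("water_survey", "data.frame")
  df
}

#' Read a survey table from CSV
#'
#' Column names are matched case-insensitively against the documented schema
#' `sample_id, source_class, pH, Na, K, Ca, Mg, Cl, SO4, HCO3, CO3, Cd, Cr,
#' Cu, Fe, Mn, Ni, Pb, Zn` (mg/L; pH unitless). Empty cells become explicit
#' `NA`. Files ending in `.gz` are decompressed transparently.
#'
#' @param path CSV file path.
#' @return A validated `water_survey`.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = "")
  as_survey(df, provenance = path)
}

#' Write a survey table to CSV
#'
#' Columns are written in documented schema order; numeric values are rendered
#' with full (round-trip) precision so that `read_survey(write_survey(x))`
#' reproduces `x` exactly. Missing values are written as empty cells. A `.gz`
#' suffix triggers gzip compression.
#'
#' @param survey A `water_survey` (or coercible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  survey <- as_survey(survey, provenance = attr(survey, "provenance") %||% "in-memory")
  out <- as.data.frame(survey)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      v <- sprintf("%.17g", out[[cn]])
      v[is.na(out[[cn]])] <- NA_character_
      out[[cn]] <- v
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}

#' @export
print.water_survey <- function(x, ...) {
  cat("Water survey: ", nrow(x), " samples (",
      paste(sprintf("%s=%d", names(table(x$source_class)),
                    as.integer(table(x$source_class))), collapse = ", "),
      ")\n", sep = "")
  cat("Provenance: ", attr(x, "provenance") %||% "unknown", "\n", sep = "")
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract the metal concentration matrix (n x 8) from a survey or a named
# vector, erroring on missing analytes rather than imputing.
metal_matrix <- function(x, metals = aq_metals) {
  if (is.numeric(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("concentration vector must be named by metal")
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  if (is.data.frame(x)) x <- as.matrix(x[intersect(names(x), metals)])
  miss <- setdiff(metals, colnames(x))
  if (length(miss))
    stop("missing metal concentration(s): ", paste(miss, collapse = ", "))
  m <- x[, metals, drop = FALSE]
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))
    stop("missing (NA) metal concentrations in row(s) ",
         paste(bad, collapse = ", "), "; explicit values are required")
  }
  storage.mode(m) <- "double"
  m
}

ion_matrix <- function(x, ions = aq_ions) {
  if (is.numeric(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("ion vector must be named")
    x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  if (is.data.frame(x)) x <- as.matrix(x[intersect(names(x), ions)])
  miss <- setdiff(ions, colnames(x))
  if (length(miss))
    stop("missing major ion(s): ", paste(miss, collapse = ", "))
  m <- x[, ions, drop = FALSE]
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))
    stop("missing (NA) ion concentrations in row(s) ",
         paste(bad, collapse = ", "))
  }
  storage.mode(m) <- "double"
  m
}
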