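#' Bio-morphometric measurement schema
#'
#' The package works on 17 linear body measurements taken with a tape measure
#' and zoometric sticks, all expressed in centimetres. The schema fixes the
#' trait codes, their descriptive names, and the canonical column order used
#' by every table the package reads or writes.
#'
#' @return A data frame with columns `code`, `long_name` and `units`
#'   (always `"cm"`), one row per measurement, in canonical order.
#' @examples
#' measurement_schema()
#' @export
measurement_schema <- function() {
  data.frame(
    code = c("HL", "HW", "HD", "HaW", "TL", "BL", "TP", "SP", "AP",
             "TW", "TD", "ThL", "RL", "RW", "RH", "IW", "NL"),
    long_name = c(
      "head length", "head width", "head depth", "height at withers",
      "total length", "body length", "thoracic perimeter",
      "shank perimeter", "abdominal perimeter", "thoracic width",
      "thoracic depth", "thoracic length", "rump length", "rump width",
      "rump height", "ischium width", "neck length"
    ),
    units = "cm",
    stringsAsFactors = FALSE
  )
}

#' Measurement trait codes in canonical order
#'
#' @return Character vector of the 17 measurement codes.
#' @export
measurement_codes <- function() measurement_schema()$code

#' Biotype levels
#'
#' The three Andean Creole cattle biotypes: Black ('Negro'), Colour-Sided
#' ('Callejon') and Brindle ('Atigrado').
#'
#' @return Character vector of the biotype tokens.
#' @export
biotype_levels <- function() c("NEGRO", "CALLEJON", "ATIGRADO")

#' Sex levels
#'
#' @return Character vector `c("FEMALE", "MALE")`.
#' @export
sex_levels <- function() c("FEMALE", "MALE")

# identity + weight columns preceding the measurements in every records table
record_id_columns <- function() c("animal_id", "biotype", "sex", "live_weight")

#' Canonical column order of a records table
#'
#' @return Character vector: identity columns followed by the 17 measurement
#'   codes in canonical order.
#' @export
record_columns <- function() c(record_id_columns(), measurement_codes())

#' Reference-population calibration
#'
#' Per-biotype trait means, overall mean, SEM and coefficient of variation
#' for the reference population the package is calibrated against: 95 adult
#' Andean Creole cattle (57 Black 'Negro', 20 Colour-Sided 'Callejon', 18
#' Brindle 'Atigrado'; 83 females, 12 males) kept under extensive highland
#' pasture at ~3900 m. These values parameterize the default synthetic herd
#' ([default_herd_config()]) and the plausibility screen
#' ([validate_record()]).
#'
#' @return A data frame with one row per measurement (canonical order) and
#'   columns `code`, `NEGRO`, `CALLEJON`, `ATIGRADO` (biotype means, cm),
#'   `overall_mean`, `overall_sem` (cm) and `cv_pct` (percent).
#' @export
creole_calibration <- function() {
  df <- data.frame(
    code = measurement_codes(),
    NEGRO    = c(50.70, 23.98, 29.02, 124.02, 200.15, 145.49, 176.57, 17.98,
                 199.96, 39.11, 67.19, 52.51, 48.00, 45.94, 125.75, 14.43, 33.51),
    CALLEJON = c(51.69, 23.06, 28.50, 124.19, 208.13, 147.88, 180.81, 18.56,
                 204.63, 39.56, 67.56, 51.94, 49.88, 48.00, 123.44, 14.75, 30.88),
    ATIGRADO = c(53.14, 24.00, 29.86, 124.50, 200.21, 144.43, 177.29, 18.36,
                 204.36, 39.00, 68.79, 54.79, 48.21, 46.07, 124.57, 14.43, 32.14),
    overall_mean = c(51.30, 23.81, 29.06, 124.13, 201.70, 145.77, 177.51, 18.16,
                     201.60, 39.18, 67.53, 52.78, 48.40, 46.36, 125.11, 14.49, 32.77),
    overall_sem  = c(0.34, 0.26, 0.34, 0.49, 1.63, 1.04, 0.88, 0.15,
                     1.30, 0.41, 0.47, 0.63, 0.31, 0.37, 1.27, 0.15, 0.41),
    cv_pct       = c(6.02, 9.83, 10.56, 3.63, 7.37, 6.49, 4.53, 7.52,
                     5.87, 9.61, 6.28, 10.92, 5.91, 7.33, 9.23, 9.42, 11.32),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$code
  df
}

#' Round half away from zero
#'
#' The rounding convention used by all 2-decimal report output (R's own
#' `round()` rounds half to even, which disagrees with how zoometric tables
#' are conventionally printed).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
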