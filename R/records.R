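#' Read per-animal measurement records from CSV
#'
#' Parses a comma-separated file with a mandatory header into a records table:
#' one row per animal with columns `animal_id`, `biotype`, `sex`, optional
#' `live_weight` (kg) and any subset of the 17 measurement codes (cm).
#' Decimal points are always `.` regardless of locale; missing values are
#' empty cells. Unknown columns are preserved as annotation columns after the
#' canonical ones. Row order is preserved.
#'
#' @param source Path to a CSV file.
#' @param aliases Optional named character vector or list mapping foreign
#'   column names to schema codes (e.g. `c(height_at_withers = "HaW")`), or
#'   the path to a YAML file of such `alias: code` pairs.
#' @return A records data frame in canonical column order (plus annotation
#'   columns), with `biotype` and `sex` as factors on their full level sets.
#' @seealso [write_records()], [validate_record()]
#' @export
read_records <- function(source, aliases = NULL) {
  if (!file.exists(source)) stop("records file not found: ", source)
  raw <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  if (!is.null(aliases)) {
    if (is.character(aliases) && length(aliases) == 1 && file.exists(aliases)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading an alias file requires the 'yaml' package")
      aliases <- unlist(yaml::read_yaml(aliases))
    }
    aliases <- unlist(aliases)
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- aliases[names(raw)[hit]]
  }

  mandatory <- c("animal_id", "biotype", "sex")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  meas_present <- intersect(measurement_codes(), names(raw))
  if (!length(meas_present))
    stop("no measurement column found; expected at least one of: ",
         paste(measurement_codes(), collapse = ", "))

  bad_bio <- !is.na(raw$biotype) & !(raw$biotype %in% biotype_levels())
  if (any(bad_bio))
    stop("unknown biotype token(s): ",
         paste(unique(raw$biotype[bad_bio]), collapse = ", "))
  bad_sex <- !is.na(raw$sex) & !(raw$sex %in% sex_levels())
  if (any(bad_sex))
    stop("unknown sex token(s): ", paste(unique(raw$sex[bad_sex]), collapse = ", "))

  numeric_cols <- c(intersect("live_weight", names(raw)), meas_present)
  for (cn in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column ", cn, " at data row ",
           paste(bad, collapse = ", "))
    raw[[cn]] <- v
    if (cn %in% meas_present) {
      neg <- which(is.finite(v) & v <= 0)
      if (length(neg))
        stop("non-positive measurement in column ", cn, " at data row ",
             paste(neg, collapse = ", "))
    }
  }
  if (!"live_weight" %in% names(raw)) raw$live_weight <- NA_real_

  raw$biotype <- factor(raw$biotype, levels = biotype_levels())
  raw$sex <- factor(raw$sex, levels = sex_levels())
  extra <- setdiff(names(raw), record_columns())
  canon <- intersect(record_columns(), names(raw))
  out <- raw[, c(canon, extra), drop = FALSE]
  for (code in setdiff(measurement_codes(), names(out))) out[[code]] <- NA_real_
  out <- out[, c(record_columns(), extra), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-animal records to CSV
#'
#' Writes records in the deterministic canonical column order (`animal_id`,
#' `biotype`, `sex`, `live_weight`, then the 17 measurement codes), with all
#' numeric cells at a fixed 4-decimal convention and missing values as empty
#' cells (never 0). Writing then reading then writing again produces a
#' byte-identical file.
#'
#' @param records A records data frame (see [read_records()]).
#' @param sink Output file path.
#' @param digits Fixed number of decimals for numeric cells.
#' @return Invisibly, the sink path.
#' @export
write_records <- function(records, sink, digits = 4) {
  cols <- record_columns()
  for (code in setdiff(cols, names(records))) records[[code]] <- NA_real_
  out <- records[, cols, drop = FALSE]
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, format = "f", digits = digits))
  for (cn in c("live_weight", measurement_codes())) out[[cn]] <- fmt(out[[cn]])
  out$biotype <- as.character(out$biotype)
  out$sex <- as.character(out$sex)
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE, na = "")
  invisible(sink)
}

#' Which measurement codes are missing from each record
#'
#' @param records A records data frame.
#' @return A list, one character vector of missing codes per row (empty for
#'   complete records).
#' @export
missing_codes <- function(records) {
  codes <- measurement_codes()
  lapply(seq_len(nrow(records)), function(i)
    codes[is.na(unlist(records[i, codes]))])
}

#' Is each record complete for a set of measurements?
#'
#' @param records A records data frame.
#' @param codes Measurement codes required; defaults to all 17.
#' @return Logical vector, one element per record.
#' @export
is_complete <- function(records, codes = measurement_codes()) {
  m <- as.matrix(records[, codes, drop = FALSE])
  apply(!is.na(m), 1, all)
}

#' Plausibility screen for one record
#'
#' Screens a record against the schema invariants and a population
#' calibration. Hard failures are non-positive or non-finite measurement
#' values; soft warnings flag values outside `mean +/- 5 SD` of the
#' calibration for that trait (SD derived from the calibration CV as
#' `cv/100 * mean`). The screen mirrors field practice of excluding animals
#' with physical defects: it flags, it never mutates or drops. Validation is
#' pure: the same record always yields the same report.
#'
#' @param record A one-row records data frame (or a records table, in which
#'   case reports are concatenated with a `row` column).
#' @param calibration Calibration data frame as from [creole_calibration()].
#' @param sd_multiplier Half-width of the plausibility band in SDs.
#' @return A data frame with columns `row`, `code`, `value`, `status`
#'   (`"hard"` or `"soft"`) and `message`; zero rows when the record is clean.
#' @export
validate_record <- function(record, calibration = creole_calibration(),
                            sd_multiplier = 5) {
  codes <- intersect(measurement_codes(), names(record))
  reports <- list()
  for (i in seq_len(nrow(record))) {
    for (code in codes) {
      v <- record[[code]][i]
      if (is.na(v)) next
      if (!is.finite(v) || v <= 0) {
        reports[[length(reports) + 1L]] <- data.frame(
          row = i, code = code, value = v, status = "hard",
          message = "non-positive or non-finite measurement",
          stringsAsFactors = FALSE)
        next
      }
      cal <- calibration[calibration$code == code, , drop = FALSE]
      if (!nrow(cal)) next
      mu <- cal$overall_mean
      sdv <- cal$cv_pct / 100 * mu
      if (v < mu - sd_multiplier * sdv || v > mu + sd_multiplier * sdv) {
        reports[[length(reports) + 1L]] <- data.frame(
          row = i, code = code, value = v, status = "soft",
          message = sprintf("outside calibration band %.2f +/- %g SD (SD = %.2f)",
                            mu, sd_multiplier, sdv),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(reports))
    return(data.frame(row = integer(), code = character(), value = numeric(),
                      status = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, reports)
}
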