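#' Zoometric index codes
#'
#' The ten classical zoometric indices, in canonical report order: cephalic
#' (CEI), thoracic (TI), body (BI), lateral body (LBI), anamorphosis (AI),
#' pelvic (PI), dactyl-thoracic (DTI), dactyl-costal (DCI), transverse pelvic
#' (TPI) and longitudinal pelvic (LPI).
#'
#' @return Character vector of the ten index codes.
#' @export
index_codes <- function() {
  c("CEI", "TI", "BI", "LBI", "AI", "PI", "DTI", "DCI", "TPI", "LPI")
}

# numerator/denominator measurement codes per ratio index (all are
# numerator/denominator * 100; AI has its own convention, see below)
index_parts <- function() {
  list(CEI = c("HW", "HL"),  TI  = c("TW", "TD"), BI  = c("BL", "TP"),
       LBI = c("HaW", "BL"), PI  = c("RW", "RL"), DTI = c("SP", "TP"),
       DCI = c("SP", "TW"),  TPI = c("RW", "HaW"), LPI = c("RL", "HaW"))
}

#' Measurements required by an index
#'
#' @param name Index code.
#' @return Character vector of measurement codes the index depends on.
#' @export
index_requirements <- function(name) {
  name <- match.arg(name, index_codes())
  if (name == "AI") c("TP", "HaW") else index_parts()[[name]]
}

#' Anamorphosis index
#'
#' Thoracic capacity relative to stature: thoracic perimeter squared over
#' height at withers. With both lengths in centimetres the value is computed
#' as `TP^2 / (100 * HaW)`, algebraically identical to `TP^2 / HaW` with both
#' lengths in metres; this is the convention under which dairy-type cattle
#' fall in the 2.5--3.0 band. The historical formula written for centimetre
#' inputs with a x100 factor (values around 25,000) is available with
#' `literal = TRUE`.
#'
#' @param TP Thoracic perimeter, cm (> 0).
#' @param HaW Height at withers, cm (> 0).
#' @param literal Use the literal centimetre x100 form instead of the
#'   metre-consistent convention.
#' @return The index value (degree-1 homogeneous in the length scale:
#'   doubling both inputs doubles it).
#' @examples
#' anamorphosis_index(177.29, 124.50) # 2.52 at 2 dp
#' @export
anamorphosis_index <- function(TP, HaW, literal = FALSE) {
  if (any(!is.finite(TP) | TP <= 0)) stop("TP must be positive and finite")
  if (any(!is.finite(HaW) | HaW <= 0)) stop("HaW must be positive and finite")
  if (literal) TP^2 / HaW * 100 else TP^2 / (100 * HaW)
}

#' Compute one zoometric index for a record
#'
#' Ratio indices are `numerator/denominator * 100`:
#' CEI = HW/HL, TI = TW/TD, BI = BL/TP, LBI = HaW/BL, PI = RW/RL,
#' DTI = SP/TP, DCI = SP/TW, TPI = RW/HaW, LPI = RL/HaW. AI follows
#' [anamorphosis_index()]. Values are returned at full floating precision;
#' rounding to 2 decimals is a reporting concern.
#'
#' @param record A one-row records data frame, or a named numeric vector/list
#'   of measurements (cm).
#' @param name Index code.
#' @param ai_literal Passed to [anamorphosis_index()] as `literal`.
#' @return The index value (scalar, or vector if `record` has several rows).
#' @examples
#' compute_index(c(RL = 48.40, HaW = 124.13), "LPI") # 38.99 at 2 dp
#' @export
compute_index <- function(record, name, ai_literal = FALSE) {
  name <- match.arg(name, index_codes())
  need <- index_requirements(name)
  get1 <- function(code) {
    if (!code %in% names(record) || all(is.na(record[[code]])))
      stop("index ", name, " requires measurement(s): ",
           paste(need, collapse = ", "), " (missing: ", code, ")")
    as.numeric(record[[code]])
  }
  vals <- lapply(need, get1)
  names(vals) <- need
  if (name == "AI")
    return(anamorphosis_index(vals$TP, vals$HaW, literal = ai_literal))
  num <- vals[[1]]; den <- vals[[2]]
  if (any(!is.na(den) & den == 0)) stop("zero denominator (", need[2],
                                        ") for index ", name)
  num / den * 100
}

#' Compute all ten indices for a record
#'
#' @inheritParams compute_index
#' @return A named numeric vector (one row) or data frame (several rows)
#'   over the ten index codes.
#' @export
compute_all_indices <- function(record, ai_literal = FALSE) {
  vals <- lapply(index_codes(), function(code)
    tryCatch(compute_index(record, code, ai_literal = ai_literal),
             error = function(e) stop("[", code, "] ", conditionMessage(e),
                                      call. = FALSE)))
  names(vals) <- index_codes()
  if (is.data.frame(record) && nrow(record) != 1)
    as.data.frame(vals)
  else
    unlist(vals)
}

#' Per-animal index table
#'
#' Computes the ten indices for every complete record; records missing any of
#' the nine measurements the indices use (HL, HW, TW, TD, BL, TP, SP, HaW,
#' RW, RL) are skipped with a warning and listed in the `skipped` attribute.
#'
#' @param records A records data frame.
#' @param ai_literal Passed to [compute_index()].
#' @return A data frame `animal_id, biotype, sex, CEI, ..., LPI` with one row
#'   per complete animal, and an attribute `skipped` holding the ids of
#'   skipped records.
#' @export
index_table <- function(records, ai_literal = FALSE) {
  needed <- unique(unlist(lapply(index_codes(), index_requirements)))
  head_cols <- c("animal_id", "biotype", "sex")
  if (nrow(records) == 0) {
    out <- records[, head_cols, drop = FALSE]
    for (code in index_codes()) out[[code]] <- numeric(0)
    attr(out, "skipped") <- character(0)
    return(out)
  }
  ok <- is_complete(records, needed)
  skipped <- records$animal_id[!ok]
  if (length(skipped))
    warning(length(skipped), " record(s) incomplete for index computation, ",
            "skipped: ", paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  kept <- records[ok, , drop = FALSE]
  out <- kept[, head_cols, drop = FALSE]
  for (code in index_codes())
    out[[code]] <- compute_index(kept, code, ai_literal = ai_literal)
  rownames(out) <- NULL
  attr(out, "skipped") <- as.character(skipped)
  out
}
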