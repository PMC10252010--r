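#' Aptitude classification thresholds
#'
#' Dimensionless cutoffs that turn index values into dairy/beef signals and
#' morphology tags. The quantified rules of the zoometric literature are the
#' defaults: the dactyl-thoracic band (dairy strictly below `dti_dairy_max`,
#' beef strictly above `dti_beef_min`, dual between), the pelvic-index beef
#' cutoffs (`> 33` for TPI and LPI), the dairy anamorphosis band
#' `[2.5, 3.0]`, the dolichocephalic cutoff (CEI `< 50`) and the
#' brachypelvic cutoff (PI `< 100`). The thoracic, body, dactyl-costal and
#' lateral-body cutoffs are not quantified in the literature the package
#' follows (only comparative language such as "the lower, the more
#' elliptical"); their defaults are heuristics chosen to reproduce the
#' qualitative reference labels and every classification row derived from
#' them is flagged `heuristic`.
#'
#' @param dti_dairy_max,dti_beef_min Dactyl-thoracic dairy/beef cutoffs.
#' @param tpi_beef_min,lpi_beef_min Transverse/longitudinal pelvic beef
#'   cutoffs.
#' @param ai_dairy_low,ai_dairy_high Dairy anamorphosis band.
#' @param cei_dolicho_max Dolichocephalic cutoff on CEI.
#' @param pi_brachy_max Brachypelvic cutoff on PI.
#' @param ti_elliptic_max Elliptical-thorax (dairy) cutoff on TI (heuristic).
#' @param bi_brevi_max Brevilineal (dairy) cutoff on BI (heuristic).
#' @param dci_dairy_min Dairy cutoff on DCI (heuristic; beef cattle show
#'   lower dactyl-costal values).
#' @param lbi_compact_max Compact/rectangular cutoff on LBI (heuristic).
#' @return A validated list of class `zoo_thresholds`.
#' @export
aptitude_thresholds <- function(dti_dairy_max = 10, dti_beef_min = 11,
                                tpi_beef_min = 33, lpi_beef_min = 33,
                                ai_dairy_low = 2.5, ai_dairy_high = 3.0,
                                cei_dolicho_max = 50, pi_brachy_max = 100,
                                ti_elliptic_max = 60, bi_brevi_max = 85,
                                dci_dairy_min = 45, lbi_compact_max = 90) {
  th <- list(dti_dairy_max = dti_dairy_max, dti_beef_min = dti_beef_min,
             tpi_beef_min = tpi_beef_min, lpi_beef_min = lpi_beef_min,
             ai_dairy_low = ai_dairy_low, ai_dairy_high = ai_dairy_high,
             cei_dolicho_max = cei_dolicho_max, pi_brachy_max = pi_brachy_max,
             ti_elliptic_max = ti_elliptic_max, bi_brevi_max = bi_brevi_max,
             dci_dairy_min = dci_dairy_min, lbi_compact_max = lbi_compact_max)
  bad <- names(th)[!vapply(th, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, TRUE)]
  if (length(bad))
    stop("thresholds must be positive finite scalars: ",
         paste(bad, collapse = ", "))
  if (th$dti_dairy_max >= th$dti_beef_min)
    stop("dti_dairy_max must be below dti_beef_min")
  if (th$ai_dairy_low >= th$ai_dairy_high)
    stop("ai_dairy_low must be below ai_dairy_high")
  structure(th, class = "zoo_thresholds")
}

# block membership of the nine aptitude-bearing indices: TI, BI, AI, DTI and
# DCI speak to milk production, LBI, PI, TPI and LPI to meat production;
# CEI is purely descriptive (skull shape)
aptitude_blocks <- function() {
  list(DAIRY = c("TI", "BI", "AI", "DTI", "DCI"),
       BEEF = c("LBI", "PI", "TPI", "LPI"))
}

#' Classify a vector of zoometric indices
#'
#' Assigns each of the ten indices a label -- `DAIRY`, `BEEF`, `DUAL` or
#' `DESCRIPTIVE` -- plus a morphology tag where one applies
#' (dolichocephalic, elliptical thorax, brevilineal, compact, brachypelvic,
#' fine skeleton). Rules, with strict inequalities throughout:
#' \itemize{
#' \item DTI: `DAIRY` below `dti_dairy_max`, `BEEF` above `dti_beef_min`,
#'   `DUAL` in between (boundaries included in the dual band).
#' \item TPI / LPI: `BEEF` above their beef cutoffs, else dairy-leaning.
#' \item AI: `DAIRY` inside the `[ai_dairy_low, ai_dairy_high]` band, else
#'   beef-leaning (thoracic capacity out of the dairy conformation range).
#' \item CEI: `DESCRIPTIVE`; tagged dolichocephalic below `cei_dolicho_max`.
#' \item PI: brachypelvic tag below `pi_brachy_max` (beef-leaning: a long,
#'   wide rump carries more meat), else dairy-leaning.
#' \item TI, BI, DCI, LBI: heuristic cutoffs (see
#'   [aptitude_thresholds()]), annotated `heuristic`.
#' }
#'
#' @param indices Named numeric vector (or one-row data frame) containing
#'   the ten index codes.
#' @param thresholds An [aptitude_thresholds()] object.
#' @return Object of class `zoo_profile`: data frame `index, value, label,
#'   block, tag, rule, heuristic`, one row per index.
#' @export
classify_indices <- function(indices, thresholds = aptitude_thresholds()) {
  if (is.data.frame(indices)) indices <- unlist(indices[1, index_codes()])
  stopifnot(all(index_codes() %in% names(indices)))
  v <- as.numeric(indices[index_codes()])
  names(v) <- index_codes()
  th <- thresholds
  row <- function(index, label, tag, rule, heuristic = FALSE)
    data.frame(index = index, value = unname(v[index]), label = label,
               block = if (index %in% aptitude_blocks()$DAIRY) "DAIRY"
                       else if (index %in% aptitude_blocks()$BEEF) "BEEF"
                       else "NONE",
               tag = tag, rule = rule, heuristic = heuristic,
               stringsAsFactors = FALSE)
  out <- rbind(
    row("CEI", "DESCRIPTIVE",
        if (v["CEI"] < th$cei_dolicho_max) "dolichocephalic" else "meso/brachycephalic",
        sprintf("dolichocephalic if < %g", th$cei_dolicho_max)),
    row("TI", if (v["TI"] < th$ti_elliptic_max) "DAIRY" else "BEEF",
        if (v["TI"] < th$ti_elliptic_max) "elliptical thorax" else "round thorax",
        sprintf("dairy if < %g", th$ti_elliptic_max), heuristic = TRUE),
    row("BI", if (v["BI"] < th$bi_brevi_max) "DAIRY" else "BEEF",
        if (v["BI"] < th$bi_brevi_max) "brevilineal" else "longilineal",
        sprintf("dairy if < %g", th$bi_brevi_max), heuristic = TRUE),
    row("LBI", if (v["LBI"] < th$lbi_compact_max) "BEEF" else "DAIRY",
        if (v["LBI"] < th$lbi_compact_max) "compact/rectangular" else "leggy",
        sprintf("beef if < %g", th$lbi_compact_max), heuristic = TRUE),
    row("AI",
        if (v["AI"] >= th$ai_dairy_low && v["AI"] <= th$ai_dairy_high)
          "DAIRY" else "BEEF",
        "", sprintf("dairy if in [%g, %g]", th$ai_dairy_low, th$ai_dairy_high)),
    row("PI", if (v["PI"] < th$pi_brachy_max) "BEEF" else "DAIRY",
        if (v["PI"] < th$pi_brachy_max) "brachypelvic" else "dolichopelvic",
        sprintf("beef (brachypelvic) if < %g", th$pi_brachy_max)),
    row("DTI",
        if (v["DTI"] < th$dti_dairy_max) "DAIRY"
        else if (v["DTI"] > th$dti_beef_min) "BEEF" else "DUAL",
        if (v["DTI"] < th$dti_dairy_max) "fine skeleton" else "",
        sprintf("dairy if < %g, beef if > %g", th$dti_dairy_max, th$dti_beef_min)),
    row("DCI", if (v["DCI"] >= th$dci_dairy_min) "DAIRY" else "BEEF", "",
        sprintf("dairy if >= %g", th$dci_dairy_min), heuristic = TRUE),
    row("TPI", if (v["TPI"] > th$tpi_beef_min) "BEEF" else "DAIRY", "",
        sprintf("beef if > %g", th$tpi_beef_min)),
    row("LPI", if (v["LPI"] > th$lpi_beef_min) "BEEF" else "DAIRY", "",
        sprintf("beef if > %g", th$lpi_beef_min))
  )
  rownames(out) <- NULL
  structure(out, class = c("zoo_profile", "data.frame"))
}

#' Overall productive-aptitude verdict
#'
#' Majority vote over the nine aptitude-bearing indices (CEI abstains). An
#' index labelled `DAIRY` or `BEEF` votes that way; an index labelled `DUAL`
#' votes with the block it belongs to by tradition (dairy block TI, BI, AI,
#' DTI, DCI; beef block LBI, PI, TPI, LPI). A unanimous vote returns `DAIRY`
#' or `BEEF`; any split returns `DUAL_DAIRY_TENDENCY` or
#' `DUAL_BEEF_TENDENCY` toward the majority, or `DUAL` on a tie (possible
#' only under user-reconfigured blocks). The verdict is a pure function of
#' the labels: raw index values play no role here.
#'
#' @param profile A [classify_indices()] result.
#' @return One of `"DAIRY"`, `"BEEF"`, `"DUAL_DAIRY_TENDENCY"`,
#'   `"DUAL_BEEF_TENDENCY"`, `"DUAL"`.
#' @export
overall_verdict <- function(profile) {
  voters <- profile[profile$block != "NONE", , drop = FALSE]
  vote <- ifelse(voters$label %in% c("DAIRY", "BEEF"), voters$label,
                 voters$block)
  d <- sum(vote == "DAIRY"); b <- sum(vote == "BEEF")
  if (b == 0 && d > 0) return("DAIRY")
  if (d == 0 && b > 0) return("BEEF")
  if (d > b) "DUAL_DAIRY_TENDENCY" else if (b > d) "DUAL_BEEF_TENDENCY"
  else "DUAL"
}
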