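#' Group-wise descriptive summaries
#'
#' Per-group and pooled mean, standard error of the mean (SEM = s/sqrt(n),
#' with s the n-1 sample standard deviation) and coefficient of variation
#' (CV% = 100 s / mean) for a set of variables. The pooled ("overall") row is
#' computed on the concatenated sample, not by averaging group statistics,
#' so a single CV column can accompany the overall mean.
#'
#' @param data A data frame holding the variables and grouping columns.
#' @param variables Character vector of numeric columns to summarize.
#' @param by Character vector of grouping columns (e.g. `"biotype"`, or
#'   `c("biotype", "sex")`); use `character(0)` for pooled-only output.
#' @param overall Include the pooled row (group label `"overall"`).
#' @return A long data frame `variable, group, n, mean, sem, cv_pct`.
#'   Groups of size 1 get `NA` SEM/CV with a warning; a zero mean makes the
#'   CV undefined and is an error.
#' @export
summarize_groups <- function(data, variables, by = "biotype", overall = TRUE) {
  stopifnot(all(variables %in% names(data)))
  key <- if (length(by)) interaction(data[by], sep = ":", drop = TRUE)
         else factor(rep("all", nrow(data)))
  one <- function(x, label, var) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) stop("empty group '", label, "' for variable ", var)
    m <- mean(x)
    if (n == 1) {
      warning("group '", label, "' has n = 1 for ", var,
              ": SEM and CV undefined")
      return(data.frame(variable = var, group = label, n = n, mean = m,
                        sem = NA_real_, cv_pct = NA_real_,
                        stringsAsFactors = FALSE))
    }
    s <- stats::sd(x)
    if (m == 0) stop("zero mean for variable ", var, " in group '", label,
                     "': CV undefined")
    data.frame(variable = var, group = label, n = n, mean = m,
               sem = s / sqrt(n), cv_pct = 100 * s / m,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (var in variables) {
    if (length(by))
      for (g in levels(key))
        rows[[length(rows) + 1L]] <- one(data[[var]][key == g], g, var)
    if (overall || !length(by))
      rows[[length(rows) + 1L]] <- one(data[[var]], "overall", var)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format summaries as a report table
#'
#' Lays out a [summarize_groups()] result the way zoometric characterization
#' tables are printed: one row per variable (measurements in schema order or
#' indices in canonical order), one `mean +/- SEM` column per group, then the
#' pooled `mean +/- SEM` and the pooled CV. Values are rounded half away from
#' zero to 2 decimals. Optional per-group significance letters are appended
#' as superscript-style suffixes.
#'
#' @param summaries Output of [summarize_groups()].
#' @param layout `"measurements"` (17 schema rows) or `"indices"` (10 index
#'   rows).
#' @param letters Optional named list: `letters[[variable]]` a named character
#'   vector of letters per group.
#' @return A character data frame; variables absent from `summaries` appear
#'   as an explicit `"--"` gap.
#' @export
format_summary_table <- function(summaries, layout = c("measurements", "indices"),
                                 letters = NULL) {
  layout <- match.arg(layout)
  vars <- if (layout == "measurements") measurement_codes() else index_codes()
  groups <- setdiff(unique(summaries$group), "overall")
  fmt <- function(m, s) sprintf("%.2f ± %.2f", round_half_up(m, 2),
                                round_half_up(s, 2))
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  cell <- function(var, g) {
    r <- summaries[summaries$variable == var & summaries$group == g, ]
    if (!nrow(r)) return("--")
    txt <- fmt(r$mean, r$sem)
    if (!is.null(letters) && !is.null(letters[[var]]) &&
        !is.na(letters[[var]][g]))
      txt <- paste(txt, letters[[var]][g])
    txt
  }
  for (g in groups) out[[g]] <- vapply(vars, cell, "", g = g)
  out[["overall"]] <- vapply(vars, cell, "", g = "overall")
  out[["cv_pct"]] <- vapply(vars, function(var) {
    r <- summaries[summaries$variable == var & summaries$group == "overall", ]
    if (!nrow(r)) "--" else sprintf("%.2f", round_half_up(r$cv_pct, 2))
  }, "")
  out
}
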