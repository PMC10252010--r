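#' Run the full zoometric characterization workflow
#'
#' Wires the stages end to end the way a characterization study proceeds:
#' records (read or simulated) -> plausibility screen -> descriptive
#' measurement summary -> per-animal indices -> index summaries (by biotype
#' and by sex within biotype) -> two-way ANOVA (biotype, sex, interaction)
#' with assumption checks -> Tukey-Kramer letters per biotype -> Pearson
#' correlation matrices -> aptitude classification of the population mean
#' index vector. Every stage writes its machine-readable CSV into
#' `out_dir`; a run manifest (JSON) records configuration and seed. Given
#' the same inputs and seed the bundle is byte-identical.
#'
#' @param input Path to a records CSV, or `NULL` to simulate.
#' @param simulate Simulate the default herd instead of reading `input`
#'   (exactly one of the two must be selected).
#' @param seed Seed for simulation.
#' @param out_dir Output directory.
#' @param alpha Significance level for letters (in `(0, 1)`).
#' @param ss_type ANOVA sums-of-squares type (1, 2 or 3).
#' @param thresholds [aptitude_thresholds()] object.
#' @param herd_config [default_herd_config()] object used when simulating.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the main in-memory results
#'   (`records`, `index_table`, `measurement_summary`, `index_summary`,
#'   `anova`, `tukey`, `correlation`, `profile`, `verdict`, `paths`).
#' @export
run_pipeline <- function(input = NULL, simulate = is.null(input), seed = 1,
                         out_dir, alpha = 0.05, ss_type = 2,
                         thresholds = aptitude_thresholds(),
                         herd_config = default_herd_config(),
                         verbose = TRUE) {
  if (is.null(input) == !simulate)
    stop("select exactly one of 'input' or 'simulate'")
  stopifnot(alpha > 0, alpha < 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[zoometry] ", ...)
  wcsv <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(format(x, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, na = "")
    path
  }
  paths <- character()

  records <- if (simulate) {
    say("simulating default herd, seed ", seed)
    simulate_herd(herd_config, seed = seed)
  } else {
    say("reading records from ", input)
    read_records(input)
  }
  say(nrow(records), " records")
  paths["records"] <- file.path(out_dir, "records.csv")
  write_records(records, paths["records"])

  screen <- validate_record(records)
  paths["screen"] <- wcsv(screen, "plausibility_screen.csv")
  say(sum(screen$status == "hard"), " hard / ",
      sum(screen$status == "soft"), " soft validation flags")

  meas_sum <- summarize_groups(records, measurement_codes(), by = "biotype")
  paths["measurement_summary"] <- wcsv(meas_sum, "measurement_summary.csv")

  idx <- index_table(records)
  paths["index_table"] <- wcsv(idx, "index_table.csv")
  say(nrow(idx), " animals in the index table (",
      length(attr(idx, "skipped")), " skipped)")

  idx_sum <- summarize_groups(idx, index_codes(), by = "biotype")
  paths["index_summary"] <- wcsv(idx_sum, "index_summary.csv")
  idx_sex <- summarize_groups(idx, index_codes(), by = c("biotype", "sex"))
  paths["index_summary_by_sex"] <- wcsv(idx_sex, "index_summary_by_sex.csv")

  say("ANOVA (type ", ss_type, " SS) + Tukey-Kramer per variable")
  anovas <- list(); tukeys <- list(); letters_meas <- list(); letters_idx <- list()
  checks <- list()
  for (set in list(list(data = records, vars = measurement_codes(),
                        tag = "measurement"),
                   list(data = idx, vars = index_codes(), tag = "index"))) {
    for (v in set$vars) {
      a <- two_way_anova(set$data, v, ss_type = ss_type)
      a$variable <- v
      anovas[[paste(set$tag, v)]] <- as.data.frame(a)
      tk <- tukey_kramer(set$data[[v]], set$data$biotype, alpha = alpha)
      tk$pairs$variable <- v
      tukeys[[paste(set$tag, v)]] <- tk$pairs
      if (set$tag == "measurement") letters_meas[[v]] <- tk$letters
      else letters_idx[[v]] <- tk$letters
      ck <- assumption_checks(set$data[[v]], set$data$biotype)
      ck$homoscedasticity$variable <- v
      checks[[paste(set$tag, v)]] <- ck$homoscedasticity
    }
  }
  paths["anova"] <- wcsv(do.call(rbind, anovas), "anova_tables.csv")
  paths["tukey"] <- wcsv(do.call(rbind, tukeys), "tukey_pairs.csv")
  paths["assumptions"] <- wcsv(do.call(rbind, checks), "assumption_checks.csv")
  lt <- do.call(rbind, lapply(names(c(letters_meas, letters_idx)), function(v) {
    L <- c(letters_meas, letters_idx)[[v]]
    data.frame(variable = v, group = names(L), letters = unname(L),
               stringsAsFactors = FALSE)
  }))
  paths["letters"] <- wcsv(lt, "tukey_letters.csv")

  say("correlation matrices")
  cm <- pearson_matrix(records[, measurement_codes()])
  paths["correlation_r"] <- wcsv(as.data.frame(cm$r), "correlation_r.csv")
  paths["correlation_p"] <- wcsv(as.data.frame(cm$p), "correlation_p.csv")

  mean_idx <- colMeans(idx[, index_codes(), drop = FALSE])
  profile <- classify_indices(mean_idx, thresholds)
  verdict <- overall_verdict(profile)
  paths["classification"] <- wcsv(as.data.frame(profile), "classification.csv")
  writeLines(verdict, file.path(out_dir, "verdict.txt"))
  paths["verdict"] <- file.path(out_dir, "verdict.txt")
  say("verdict: ", verdict)

  pretty_meas <- format_summary_table(meas_sum, "measurements",
                                      letters = letters_meas)
  pretty_idx <- format_summary_table(idx_sum, "indices", letters = letters_idx)
  paths["table_measurements"] <- wcsv(pretty_meas, "table_measurements.csv")
  paths["table_indices"] <- wcsv(pretty_idx, "table_indices.csv")

  manifest <- list(simulate = simulate, input = input, seed = seed,
                   alpha = alpha, ss_type = ss_type,
                   thresholds = unclass(thresholds),
                   n_records = nrow(records), verdict = verdict,
                   outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["manifest"] <- file.path(out_dir, "run_manifest.json")

  invisible(list(records = records, index_table = idx,
                 measurement_summary = meas_sum, index_summary = idx_sum,
                 index_summary_by_sex = idx_sex, anova = anovas,
                 tukey = tukeys, letters = c(letters_meas, letters_idx),
                 correlation = cm, profile = profile, verdict = verdict,
                 paths = paths))
}
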