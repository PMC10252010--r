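# shared fixtures built in code

# a complete record at the overall calibration means
mean_record <- function() {
  cal <- creole_calibration()
  rec <- as.data.frame(as.list(stats::setNames(cal$overall_mean, cal$code)))
  cbind(data.frame(animal_id = "M0", biotype = "NEGRO", sex = "FEMALE",
                   live_weight = NA_real_, stringsAsFactors = FALSE), rec)
}

# small deterministic herd for structural tests
small_herd <- function(seed = 1, n_per_cell = NULL) {
  cfg <- default_herd_config()
  if (!is.null(n_per_cell)) cfg$cells$n <- n_per_cell
  simulate_herd(cfg, seed = seed)
}

# unbalanced 12-row two-factor worked dataset; the frozen sums of squares in
# test-inference.R come from an independent Type-II computation on it
worked_anova_data <- function() {
  data.frame(
    A = factor(c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2", "a2",
                 "a3", "a3", "a3")),
    B = factor(c("f", "f", "m", "m", "f", "f", "f", "m", "m", "f", "m", "m")),
    y = c(10.1, 11.3, 12.0, 12.8, 9.4, 10.2, 9.9, 11.5, 12.2, 8.7, 10.9, 11.4))
}

# reference zoometric index means for the calibration population
reference_index_means <- function() {
  c(CEI = 46.53, TI = 58.15, BI = 82.19, LBI = 85.47, AI = 2.55,
    PI = 95.85, DTI = 10.24, DCI = 46.7, TPI = 37.36, LPI = 38.99)
}
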