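test_that("the default configuration encodes the reference population", {
  cfg <- default_herd_config()
  expect_equal(sum(cfg$cells$n), 95)
  expect_equal(cfg$cells$n[cfg$cells$sex == "FEMALE"], c(53, 16, 14))
  expect_equal(cfg$cells$n[cfg$cells$sex == "MALE"], c(4, 4, 4))
  expect_equal(cfg$means["HL", "NEGRO"], 50.70)
  expect_equal(cfg$means["HaW", "ATIGRADO"], 124.50)
  expect_equal(unname(cfg$cv_pct["HaW"]), 3.63)
  # head width is uncorrelated with every other trait in the target
  hw <- cfg$correlation_target["HW", ]
  expect_equal(unname(hw[setdiff(names(hw), "HW")]),
               rep(0, 16))
  expect_equal(unname(cfg$correlation_target["HD", "TD"]), -0.6)
})

test_that("nearest_correlation fixes indefinite targets and leaves PD inputs alone", {
  expect_equal(nearest_correlation(diag(4)), diag(4), tolerance = 1e-9)

  # all off-diagonals 0.9: eigenvalues 2.8, 0.1, 0.1 -- already PD
  R <- matrix(0.9, 3, 3); diag(R) <- 1
  expect_equal(sort(eigen(R)$values), c(0.1, 0.1, 2.8), tolerance = 1e-12)
  expect_equal(nearest_correlation(R), R, tolerance = 1e-7)

  # flipping one sign makes it indefinite; the repair must be PD and close
  R2 <- R; R2[1, 3] <- R2[3, 1] <- -0.9
  expect_lt(min(eigen(R2)$values), 0)
  fixed <- nearest_correlation(R2)
  expect_gte(min(eigen(fixed)$values), 1e-9)
  expect_equal(diag(fixed), rep(1, 3))
  expect_equal(fixed, t(fixed))
  expect_lt(max(abs(fixed - R2)), 0.5)

  expect_error(nearest_correlation(matrix(c(1, 0.2, 0.3, 1), 2, 2)),
               "symmetric")
  Rd <- diag(3); Rd[1, 1] <- 2
  expect_error(nearest_correlation(Rd), "unit diagonal")
})

test_that("nearest_correlation matches the established PD repair", {
  skip_if_not_installed("Matrix")
  cfg <- default_herd_config()
  ref <- as.matrix(Matrix::nearPD(cfg$correlation_target, corr = TRUE,
                                  conv.tol = 1e-12)$mat)
  expect_equal(cfg$correlation, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("simulation is bit-reproducible and respects the schema", {
  h1 <- simulate_herd(default_herd_config(), seed = 42)
  h2 <- simulate_herd(default_herd_config(), seed = 42)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 95)
  expect_identical(names(h1), record_columns())
  expect_true(all(is_complete(h1)))
  expect_true(all(as.matrix(h1[, measurement_codes()]) > 0))
  h3 <- simulate_herd(default_herd_config(), seed = 43)
  expect_false(identical(h1, h3))
})

test_that("simulate_herd does not disturb the caller's RNG stream", {
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_herd(seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("large-sample moments recover the configured means, CVs and correlations", {
  cfg <- default_herd_config(n_override = 60000)
  h <- simulate_herd(cfg, seed = 17)
  expect_equal(nrow(h), 60000)
  # pooled HaW mean near the size-weighted target
  w <- cfg$cells$n / sum(cfg$cells$n)
  target <- sum(w * cfg$means["HaW", cfg$cells$biotype])
  expect_lt(abs(mean(h$HaW) - target), 0.2)
  # per-biotype mean and CV within 0.2% of mean / close to target CV
  neg <- h[h$biotype == "NEGRO", ]
  expect_lt(abs(mean(neg$TP) - 176.57), 0.002 * 176.57)
  expect_equal(100 * sd(neg$TP) / mean(neg$TP), 4.53, tolerance = 0.05)
  # configured correlation recovered
  r_emp <- cor(neg$HL, neg$HaW)
  r_cfg <- default_herd_config()$correlation["HL", "HaW"]
  expect_lt(abs(r_emp - r_cfg), 0.05)
})

test_that("sample correlation signs match the target for every strong pair", {
  cfg <- default_herd_config(n_override = 5000)
  h <- simulate_herd(cfg, seed = 23)
  emp <- cor(as.matrix(h[, measurement_codes()]))
  tgt <- cfg$correlation_target
  strong <- which(abs(tgt) >= 0.5 & row(tgt) < col(tgt), arr.ind = TRUE)
  for (k in seq_len(nrow(strong))) {
    i <- strong[k, 1]; j <- strong[k, 2]
    expect_identical(sign(emp[i, j]), sign(tgt[i, j]),
                     label = paste(rownames(tgt)[i], colnames(tgt)[j]))
  }
})

test_that("means too close to zero for their CV trigger the rejection warning", {
  cal <- creole_calibration()
  means <- as.matrix(cal[, biotype_levels()])
  rownames(means) <- cal$code
  cfg <- default_herd_config(
    cv_pct = stats::setNames(rep(60, 17), cal$code), n_override = 400)
  expect_warning(simulate_herd(cfg, seed = 2), "rejection rate")
})

test_that("herd files round-trip records, configuration and seed", {
  dir <- withr::local_tempdir()
  cfg <- default_herd_config()
  h <- simulate_herd(cfg, seed = 12)
  paths <- herd_to_files(h, dir, cfg, seed = 12)
  expect_true(all(file.exists(paths)))
  back <- read_records(paths["herd"])
  for (cn in record_columns()) expect_equal(back[[cn]], h[[cn]], info = cn)

  man <- read_herd_manifest(paths["manifest"])
  expect_equal(man$seed, 12)
  expect_equal(man$config$cells$n, cfg$cells$n)
  expect_equal(man$config$means, cfg$means, tolerance = 1e-12)
  expect_equal(man$config$cv_pct, cfg$cv_pct)
  expect_equal(man$config$correlation, cfg$correlation, tolerance = 1e-9)
  # regenerating from the manifest reproduces the records
  h2 <- simulate_herd(man$config, seed = man$seed)
  expect_identical(h2[, measurement_codes()], h[, measurement_codes()])

  # determinism extends to the files themselves
  dir2 <- withr::local_tempdir()
  herd_to_files(h2, dir2, man$config, seed = 12)
  expect_identical(readLines(file.path(dir, "herd.csv")),
                   readLines(file.path(dir2, "herd.csv")))

  # an empty herd still writes a header-only CSV
  herd_to_files(h[0, ], withr::local_tempdir(), cfg, seed = 1)
})
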