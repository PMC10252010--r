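#' Default trait-correlation specification
#'
#' Sparse list of trait pairs with target Pearson correlations encoding the
#' qualitative correlation structure reported for the reference population:
#' strong positive relationships (0.7) e.g. between head length and height at
#' withers, abdominal perimeter and rump length; intermediate positives (0.5)
#' e.g. among the trunk perimeters and the rump dimensions; one strong
#' negative (-0.6) between head depth and thoracic depth; a weak negative
#' (-0.3) between thoracic length and ischium width; and no correlation at
#' all between head width and any other trait. Unlisted pairs default to 0.
#' Exact coefficients for the population are unpublished, so the magnitudes
#' are configuration, not constants.
#'
#' @return Data frame `trait1, trait2, rho`.
#' @export
default_correlation_spec <- function() {
  p <- function(a, b, rho) data.frame(trait1 = a, trait2 = b, rho = rho,
                                      stringsAsFactors = FALSE)
  strong <- 0.7; inter <- 0.5
  rbind(
    p("HL", c("HaW", "AP", "RL"), strong),
    p("HaW", c("TL", "SP", "AP", "TW", "RW", "RL"), strong),
    p("TL", c("BL", "TP", "SP", "AP", "RL"), inter),
    p("BL", c("TP", "AP", "RL"), strong),
    p("TP", c("AP", "RL", "RW"), inter),
    p("SP", c("AP", "RW"), inter),
    p("AP", c("TW", "ThL", "RW"), inter),
    p("TW", c("TD", "RW", "RL", "NL"), inter),
    p("TD", c("RW", "RL"), strong),
    p("HD", "TD", -0.6),
    p("ThL", "IW", -0.3),
    p("RW", "RL", inter)
  )
}

#' Assemble a full correlation target from a sparse specification
#'
#' @param spec Data frame `trait1, trait2, rho` (see
#'   [default_correlation_spec()]); pairs must reference schema codes, no
#'   self-pairs, values in `[-1, 1]`.
#' @param codes Trait codes defining the matrix dimension/order.
#' @return Symmetric unit-diagonal matrix over `codes` (not necessarily
#'   positive definite; see [nearest_correlation()]).
#' @export
build_correlation_target <- function(spec = default_correlation_spec(),
                                     codes = measurement_codes()) {
  stopifnot(all(c(spec$trait1, spec$trait2) %in% codes),
            all(spec$trait1 != spec$trait2),
            all(abs(spec$rho) <= 1))
  R <- diag(length(codes))
  dimnames(R) <- list(codes, codes)
  for (i in seq_len(nrow(spec))) {
    R[spec$trait1[i], spec$trait2[i]] <- spec$rho[i]
    R[spec$trait2[i], spec$trait1[i]] <- spec$rho[i]
  }
  R
}

#' Nearest positive-definite correlation matrix
#'
#' Alternating-projections (Higham-style) repair of an indefinite
#' correlation target: iterate between the positive-semidefinite cone
#' (eigenvalue clipping, with a Dykstra correction) and the unit-diagonal
#' affine set until the iterates stabilize, then floor the eigenvalues at
#' `eig_floor` and rescale to unit diagonal. Already-PD inputs are returned
#' unchanged up to tolerance (the projections fix them).
#'
#' @param R Symmetric matrix with unit diagonal and entries in `[-1, 1]`.
#' @param eig_floor Minimum eigenvalue of the result.
#' @param tol Convergence tolerance on the iterate change (max-abs).
#' @param maxit Iteration cap.
#' @return A symmetric positive-definite correlation matrix of the same
#'   dimension and dimnames.
#' @export
nearest_correlation <- function(R, eig_floor = 1e-8, tol = 1e-10,
                                maxit = 500) {
  if (!is.matrix(R) || nrow(R) != ncol(R) || !isSymmetric(R, tol = 1e-12))
    stop("R must be a symmetric square matrix")
  if (any(abs(diag(R) - 1) > 1e-12)) stop("R must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12)) stop("entries of R must lie in [-1, 1]")
  Y <- R
  DS <- matrix(0, nrow(R), ncol(R))
  for (it in seq_len(maxit)) {
    Rk <- Y - DS
    e <- eigen(Rk, symmetric = TRUE)
    X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    X <- (X + t(X)) / 2
    DS <- X - Rk
    Ynew <- X
    diag(Ynew) <- 1
    if (max(abs(Ynew - Y)) < tol) { Y <- Ynew; break }
    Y <- Ynew
  }
  e <- eigen(Y, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  Y <- e$vectors %*% (vals * t(e$vectors))
  Y <- (Y + t(Y)) / 2
  d <- sqrt(diag(Y))
  Y <- Y / tcrossprod(d)
  diag(Y) <- 1
  dimnames(Y) <- dimnames(R)
  Y
}

#' Default synthetic-herd configuration
#'
#' Fully parameterizes the synthetic population the package uses as a
#' stand-in for the reference herd: biotype-by-sex cell sizes 53/16/14
#' females and 4/4/4 males (95 animals), per-biotype trait means and
#' per-trait CVs from [creole_calibration()], the repaired default
#' correlation target, and a per-trait male multiplier of 1.0 (per-sex
#' measurement means are not published for the reference population; the
#' multiplier supports sensitivity tests).
#'
#' @param cells Data frame `biotype, sex, n`.
#' @param means Matrix of trait means, traits x biotypes (cm).
#' @param cv_pct Named per-trait CV vector (percent), applied within biotype.
#' @param correlation_spec Sparse correlation specification.
#' @param male_multiplier Scalar or named per-trait multiplier on male means.
#' @param n_override If non-`NULL`, total herd size: cell sizes are rescaled
#'   proportionally (largest-remainder rounding).
#' @return Object of class `zoo_herd_config`; `$correlation` holds the
#'   PD-repaired matrix, `$correlation_target` the raw target.
#' @export
default_herd_config <- function(cells = NULL, means = NULL, cv_pct = NULL,
                                correlation_spec = default_correlation_spec(),
                                male_multiplier = 1.0, n_override = NULL) {
  cal <- creole_calibration()
  if (is.null(cells))
    cells <- data.frame(
      biotype = rep(biotype_levels(), 2),
      sex = rep(sex_levels(), each = 3),
      n = c(53, 16, 14, 4, 4, 4), stringsAsFactors = FALSE)
  if (is.null(means)) {
    means <- as.matrix(cal[, biotype_levels()])
    rownames(means) <- cal$code
  }
  if (is.null(cv_pct)) cv_pct <- stats::setNames(cal$cv_pct, cal$code)
  stopifnot(all(cells$n >= 0), all(means > 0), all(cv_pct > 0))
  if (length(male_multiplier) == 1)
    male_multiplier <- stats::setNames(rep(male_multiplier,
                                           length(rownames(means))),
                                       rownames(means))
  target <- build_correlation_target(correlation_spec, rownames(means))
  structure(list(cells = cells, means = means, cv_pct = cv_pct,
                 correlation_spec = correlation_spec,
                 correlation_target = target,
                 correlation = nearest_correlation(target),
                 male_multiplier = male_multiplier,
                 n_override = n_override),
            class = "zoo_herd_config")
}

# proportional cell rescaling with largest-remainder rounding
rescale_cells <- function(cells, n_total) {
  raw <- cells$n / sum(cells$n) * n_total
  base <- floor(raw)
  short <- n_total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  cells$n <- as.integer(base)
  cells
}

#' Simulate a herd of animal records
#'
#' Draws each biotype-by-sex cell from a multivariate Gaussian with mean
#' vector = biotype trait means (times the male multiplier for males) and
#' covariance `D R D`, where `D = diag(cv/100 * mean)` and `R` is the
#' PD-repaired correlation matrix. Draws with any non-positive coordinate
#' are rejected and redrawn (with the largest CV at 11.32% this truncation
#' is negligible); a rejection rate above 1% raises a configuration
#' warning. Measurements are recorded to 0.1 cm, the precision of a field
#' tape measure. A fixed seed makes the output bit-reproducible.
#'
#' @param config A [default_herd_config()] object.
#' @param seed Integer seed governing all draws.
#' @return A records data frame (see [read_records()]) in canonical column
#'   order; `live_weight` is left empty (weight is not simulated).
#' @export
simulate_herd <- function(config = default_herd_config(), seed = 1) {
  stopifnot(inherits(config, "zoo_herd_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  cells <- config$cells
  if (!is.null(config$n_override))
    cells <- rescale_cells(cells, config$n_override)
  codes <- rownames(config$means)
  R <- config$correlation
  total_draws <- 0L
  total_rejected <- 0L
  blocks <- list()
  for (i in seq_len(nrow(cells))) {
    n <- cells$n[i]
    if (n == 0) next
    bio <- cells$biotype[i]; sex <- cells$sex[i]
    mu <- config$means[, bio]
    if (sex == "MALE") mu <- mu * config$male_multiplier[codes]
    sdv <- config$cv_pct[codes] / 100 * mu
    Sigma <- R * tcrossprod(sdv)
    draw <- function(m) MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
    X <- matrix(draw(n), ncol = length(codes))
    total_draws <- total_draws + n
    repeat {
      bad <- which(apply(X <= 0, 1, any))
      if (!length(bad)) break
      total_rejected <- total_rejected + length(bad)
      total_draws <- total_draws + length(bad)
      X[bad, ] <- matrix(draw(length(bad)), ncol = length(codes))
    }
    colnames(X) <- codes
    X <- round(X, 1)
    blk <- data.frame(
      animal_id = sprintf("%s-%s-%03d", substr(bio, 1, 1),
                          substr(sex, 1, 1), seq_len(n)),
      biotype = factor(bio, levels = biotype_levels()),
      sex = factor(sex, levels = sex_levels()),
      live_weight = NA_real_, stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- cbind(blk, as.data.frame(X))
  }
  out <- do.call(rbind, blocks)
  if (total_rejected / max(total_draws, 1) > 0.01)
    warning(sprintf(paste0("rejection rate %.1f%% exceeds 1%%: trait means ",
                           "too close to zero relative to their CV"),
                    100 * total_rejected / total_draws))
  out <- out[, record_columns(), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated herd with its manifest
#'
#' Writes the records CSV (via [write_records()]) plus a JSON manifest
#' recording the full configuration and seed, so a run can be reproduced
#' from the file set alone. Re-running with the same seed and configuration
#' produces identical files.
#'
#' @param records Records data frame.
#' @param directory Output directory (created if needed).
#' @param config The generating [default_herd_config()] object.
#' @param seed The seed the records were drawn with.
#' @return Invisibly, named character vector of the written paths.
#' @export
herd_to_files <- function(records, directory, config, seed) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  herd_path <- file.path(directory, "herd.csv")
  write_records(records, herd_path)
  manifest <- list(
    seed = as.integer(seed),
    n_animals = nrow(records),
    cells = config$cells,
    means = as.data.frame(config$means),
    trait_order = rownames(config$means),
    cv_pct = as.list(config$cv_pct),
    correlation_spec = config$correlation_spec,
    male_multiplier = as.list(config$male_multiplier),
    n_override = config$n_override)
  man_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(herd = herd_path, manifest = man_path))
}

#' Rebuild a herd configuration from a manifest
#'
#' @param path Path to a `manifest.json` written by [herd_to_files()].
#' @return List with `config` (a rebuilt `zoo_herd_config`) and `seed`.
#' @export
read_herd_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(m$means)
  rownames(means) <- m$trait_order
  config <- default_herd_config(
    cells = m$cells, means = means,
    cv_pct = unlist(m$cv_pct),
    correlation_spec = m$correlation_spec,
    male_multiplier = unlist(m$male_multiplier),
    n_override = if (length(m$n_override)) m$n_override else NULL)
  list(config = config, seed = m$seed)
}
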