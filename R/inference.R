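#' Two-factor analysis of variance for unbalanced designs
#'
#' Fits `y ~ A + B + A:B` by least squares and decomposes the sums of squares
#' by nested-model comparison. With group sizes as unequal as 57/20/18
#' biotypes and 83/12 sexes the SS type matters: the default is Type II
#' (each main effect adjusted for the other; the interaction tested last),
#' with Type I (sequential, in `A, B, A:B` order) and Type III (each term
#' adjusted for all others, sum-to-zero contrasts) available. F for every
#' term uses the full-model residual mean square.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns; set
#'   `factor_b = NULL` for a one-way analysis of `factor_a`.
#' @param ss_type 1, 2 or 3.
#' @param interaction Include the `A:B` term. A biotype-by-sex cell with no
#'   animals makes the interaction inestimable: this is an error pointing to
#'   `interaction = FALSE` (main effects only).
#' @return An object of class `zoo_anova`: a data frame `term, ss, df, ms,
#'   statistic, p`, with the residual row last, plus attributes `response`,
#'   `ms_res`, `df_res` and the model frame. A constant response yields zero
#'   SS and `NaN` F/p with a warning.
#' @export
two_way_anova <- function(data, response, factor_a = "biotype",
                          factor_b = "sex", ss_type = 2, interaction = TRUE) {
  stopifnot(response %in% names(data), factor_a %in% names(data))
  one_way <- is.null(factor_b)
  if (!one_way) stopifnot(factor_b %in% names(data))
  y <- data[[response]]
  A <- droplevels(factor(data[[factor_a]]))
  keep <- !is.na(y) & !is.na(A)
  if (!one_way) {
    B <- droplevels(factor(data[[factor_b]]))
    keep <- keep & !is.na(B)
  }
  y <- y[keep]; A <- droplevels(A[keep])
  if (nlevels(A) < 2) stop("factor ", factor_a, " needs >= 2 observed levels")
  if (!one_way) {
    B <- droplevels(B[keep])
    if (nlevels(B) < 2) stop("factor ", factor_b, " needs >= 2 observed levels")
    if (interaction && any(table(A, B) == 0))
      stop("empty ", factor_a, " x ", factor_b, " cell: interaction ",
           "inestimable; rerun with interaction = FALSE for main effects only")
  }
  if (stats::var(y) == 0) warning("constant response: F and p undefined")

  rss <- function(fit) sum(stats::residuals(fit)^2)
  df <- data.frame(y = y, A = A)
  if (one_way) {
    fit <- stats::lm(y ~ A, data = df)
    ss_a <- rss(stats::lm(y ~ 1, data = df)) - rss(fit)
    tab <- data.frame(term = factor_a, ss = ss_a, df = nlevels(A) - 1,
                      stringsAsFactors = FALSE)
    full <- fit
  } else {
    df$B <- B
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    form_full <- if (interaction) y ~ A * B else y ~ A + B
    full <- stats::lm(form_full, data = df)
    f_ab <- stats::lm(y ~ A + B, data = df)
    f_a <- stats::lm(y ~ A, data = df)
    f_b <- stats::lm(y ~ B, data = df)
    f_0 <- stats::lm(y ~ 1, data = df)
    ss <- switch(as.character(ss_type),
      "1" = c(A = rss(f_0) - rss(f_a), B = rss(f_a) - rss(f_ab)),
      "2" = c(A = rss(f_b) - rss(f_ab), B = rss(f_a) - rss(f_ab)),
      "3" = {
        X <- stats::model.matrix(full)
        asg <- attr(X, "assign")
        drop_term <- function(k) {
          Xr <- X[, asg != k, drop = FALSE]
          sum(stats::lm.fit(Xr, y)$residuals^2) - rss(full)
        }
        c(A = drop_term(1), B = drop_term(2))
      },
      stop("ss_type must be 1, 2 or 3"))
    tab <- data.frame(term = c(factor_a, factor_b),
                      ss = pmax(unname(ss), 0),
                      df = c(nlevels(A) - 1, nlevels(B) - 1),
                      stringsAsFactors = FALSE)
    if (interaction) {
      tab <- rbind(tab, data.frame(
        term = paste0(factor_a, ":", factor_b),
        ss = max(rss(f_ab) - rss(full), 0),
        df = stats::df.residual(f_ab) - stats::df.residual(full)))
    }
  }
  df_res <- stats::df.residual(full)
  ss_res <- rss(full)
  tab$ms <- tab$ss / tab$df
  ms_res <- ss_res / df_res
  tab$statistic <- tab$ms / ms_res
  tab$p <- stats::pf(tab$statistic, tab$df, df_res, lower.tail = FALSE)
  if (stats::var(y) == 0) {
    tab$ss <- 0; tab$ms <- 0; ss_res <- 0; ms_res <- 0
    tab$statistic <- NaN; tab$p <- NaN
  }
  tab <- rbind(tab, data.frame(term = "residual", ss = ss_res, df = df_res,
                               ms = ms_res, statistic = NA_real_, p = NA_real_))
  rownames(tab) <- NULL
  structure(tab, class = c("zoo_anova", "data.frame"), response = response,
            ms_res = ms_res, df_res = df_res,
            model = if (one_way) df[c("y", "A")] else df)
}

#' Tukey-Kramer pairwise comparisons with compact letter display
#'
#' All-pairs comparison of group means against the studentized range
#' distribution. With unequal group sizes the Tukey-Kramer standard error
#' `sqrt(MS_res/2 * (1/n_i + 1/n_j))` is used; the residual mean square
#' defaults to the pooled within-group variance (one-way residual), or can be
#' supplied (e.g. from [two_way_anova()]). Letters are assigned by
#' insert-and-absorb so that two groups share a letter exactly when their
#' adjusted p exceeds `alpha`.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group membership, `k >= 2` levels,
#'   each with `n >= 2`.
#' @param alpha Significance level for the letter display.
#' @param ms_res,df_res Optional residual mean square and its df; both or
#'   neither.
#' @return An object of class `zoo_tukey`: list with `pairs` (data frame
#'   `group1, group2, diff, se, q, p_adj`, `diff = mean(group2) -
#'   mean(group1)`), `letters` (named character vector, groups in increasing
#'   mean order get letters in alphabet order), `means`, `n`, `ms_res`,
#'   `df_res`, `alpha`. If the residual variance is zero, identical means
#'   share one letter and differing means are separated with `p_adj = 0`.
#' @export
tukey_kramer <- function(values, groups, alpha = 0.05,
                         ms_res = NULL, df_res = NULL) {
  g <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  n <- tabulate(g)
  if (any(n < 2)) stop("every group needs n >= 2")
  means <- tapply(values, g, mean)
  if (is.null(ms_res) != is.null(df_res))
    stop("supply both ms_res and df_res, or neither")
  if (is.null(ms_res)) {
    df_res <- sum(n - 1)
    ms_res <- sum(tapply(values, g, function(x) sum((x - mean(x))^2))) / df_res
  }
  lev <- levels(g)
  pr <- utils::combn(k, 2)
  diff <- means[pr[2, ]] - means[pr[1, ]]
  se <- sqrt(ms_res / 2 * (1 / n[pr[1, ]] + 1 / n[pr[2, ]]))
  q <- abs(diff) / se
  p_adj <- ifelse(se == 0, ifelse(diff == 0, 1, 0),
                  stats::ptukey(q, k, df_res, lower.tail = FALSE))
  pairs <- data.frame(group1 = lev[pr[1, ]], group2 = lev[pr[2, ]],
                      diff = unname(diff), se = unname(se), q = unname(q),
                      p_adj = unname(p_adj), stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (j in seq_len(ncol(pr))) {
    s <- pairs$p_adj[j] <= alpha
    sig[pr[1, j], pr[2, j]] <- s
    sig[pr[2, j], pr[1, j]] <- s
  }
  letters <- compact_letters(sig, order_by = means)
  structure(list(pairs = pairs, letters = letters,
                 means = stats::setNames(as.numeric(means), lev),
                 n = stats::setNames(n, lev), ms_res = ms_res,
                 df_res = df_res, alpha = alpha),
            class = "zoo_tukey")
}

#' Compact letter display from a significance pattern
#'
#' Insert-and-absorb letter assignment: starting from one column holding all
#' groups, every significantly different pair splits each column containing
#' both, and columns contained in another are absorbed. The result satisfies,
#' for every pair of groups, share-a-letter if and only if the pair is not
#' significantly different.
#'
#' @param sig Symmetric logical matrix with group dimnames; `TRUE` marks a
#'   significantly different pair.
#' @param order_by Optional numeric vector (e.g. group means): letters are
#'   ordered so the group with the smallest value carries `"a"`.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(sig, order_by = NULL) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  k <- nrow(sig)
  groups <- rownames(sig)
  if (is.null(groups)) groups <- as.character(seq_len(k))
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    new_cols <- list()
    for (cc in cols) {
      if (i %in% cc && j %in% cc)
        new_cols <- c(new_cols, list(setdiff(cc, i)), list(setdiff(cc, j)))
      else new_cols <- c(new_cols, list(cc))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_cols[[a]] %in% new_cols[[b]]) &&
          !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b))
        keep[a] <- FALSE
    }
    cols <- new_cols[keep]
  }
  ord <- if (is.null(order_by)) seq_len(k) else order(order_by)
  rank_of <- match(seq_len(k), ord)
  cols <- cols[order(vapply(cols, function(cc) min(rank_of[cc]), 0))]
  out <- vapply(seq_len(k), function(g)
    paste(letters[which(vapply(cols, function(cc) g %in% cc, TRUE))],
          collapse = ""), "")
  stats::setNames(out, groups)
}

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from
#' `t = r sqrt((n-2)/(1-r^2))` on `n-2` df. Zero-variance variables give
#' `NA` correlations with a warning. No multiplicity correction is applied
#' by default (per-pair significance reporting); `adjust` applies
#' [stats::p.adjust()] over the strictly-upper-triangle p-values.
#'
#' @param table Data frame or matrix of numeric variables.
#' @param adjust One of `"none"`, `"holm"`, `"bonferroni"`.
#' @return An object of class `zoo_cor`: list with matrices `r`, `p`, `n`
#'   and the `variables` name vector. `r` has unit diagonal, is symmetric,
#'   and entries lie in `[-1, 1]`.
#' @export
pearson_matrix <- function(table, adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  m <- as.matrix(as.data.frame(table))
  storage.mode(m) <- "double"
  vars <- colnames(m)
  zerovar <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE)) == 0
  if (any(zerovar, na.rm = TRUE))
    warning("zero-variance variable(s): ",
            paste(vars[which(zerovar)], collapse = ", "),
            "; correlations reported as NA")
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- ifelse(is.na(diag(r)) & zerovar, NA, 1)
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(r))
  nmat <- p
  for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) {
    nij <- sum(stats::complete.cases(m[, c(i, j)]))
    nmat[i, j] <- nij
    if (i == j) { p[i, j] <- 0; next }
    rij <- r[i, j]
    if (is.na(rij) || nij < 3) next
    if (abs(rij) == 1) { p[i, j] <- 0; next }
    tt <- rij * sqrt((nij - 2) / (1 - rij^2))
    p[i, j] <- 2 * stats::pt(abs(tt), nij - 2, lower.tail = FALSE)
  }
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, n = nmat, variables = vars),
            class = "zoo_cor")
}

#' Normality and homoscedasticity checks
#'
#' Advisory pre-ANOVA checks: Shapiro-Wilk per group (n between 3 and 5000,
#' non-constant) and the Brown-Forsythe test across groups (one-way ANOVA on
#' absolute deviations from group medians). The pipeline proceeds regardless
#' of the outcome; the report is for the analyst.
#'
#' @param values Numeric response vector.
#' @param groups Group membership.
#' @return List with `normality` (data frame `group, n, statistic, p,
#'   note`) and `homoscedasticity` (data frame `statistic, df1, df2, p`,
#'   `NA` with a note when degenerate).
#' @export
assumption_checks <- function(values, groups) {
  g <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  norm <- do.call(rbind, lapply(levels(g), function(lv) {
    x <- values[g == lv]
    if (length(x) < 3 || length(x) > 5000)
      return(data.frame(group = lv, n = length(x), statistic = NA_real_,
                        p = NA_real_,
                        note = if (length(x) < 3) "n < 3"
                               else "n > 5000: Shapiro-Wilk not applicable",
                        stringsAsFactors = FALSE))
    if (stats::var(x) == 0)
      return(data.frame(group = lv, n = length(x), statistic = NA_real_,
                        p = NA_real_, note = "constant sample",
                        stringsAsFactors = FALSE))
    sw <- stats::shapiro.test(x)
    data.frame(group = lv, n = length(x), statistic = unname(sw$statistic),
               p = sw$p.value, note = "", stringsAsFactors = FALSE)
  }))
  ad <- abs(values - stats::ave(values, g, FUN = stats::median))
  homo <- if (nlevels(g) < 2 || stats::var(ad) == 0) {
    data.frame(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
               p = NA_real_, note = "degenerate (one group or constant)",
               stringsAsFactors = FALSE)
  } else {
    av <- stats::anova(stats::lm(ad ~ g))
    data.frame(statistic = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
               p = av$`Pr(>F)`[1], note = "", stringsAsFactors = FALSE)
  }
  list(normality = norm, homoscedasticity = homo)
}
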