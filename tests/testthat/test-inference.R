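test_that("worked 12-row unbalanced dataset matches the frozen Type II oracle", {
  d <- worked_anova_data()
  a <- two_way_anova(d, "y", "A", "B", ss_type = 2)
  # frozen values from an independent Type-II computation on this dataset
  expect_equal(a$ss[a$term == "A"], 4.07147286822, tolerance = 1e-9)
  expect_equal(a$ss[a$term == "B"], 11.54680620155, tolerance = 1e-9)
  expect_equal(a$ss[a$term == "A:B"], 0.22519379845, tolerance = 1e-9)
  expect_equal(a$ss[a$term == "residual"], 1.73666666667, tolerance = 1e-9)
  expect_equal(a$statistic[a$term == "A"], 7.03325, tolerance = 1e-5)
  expect_equal(a$p[a$term == "B"], 0.00073553, tolerance = 1e-4)

  a1 <- two_way_anova(d, "y", "A", "B", ss_type = 1)
  expect_equal(a1$ss[a1$term == "A"], 2.978, tolerance = 1e-9)
  a3 <- two_way_anova(d, "y", "A", "B", ss_type = 3)
  expect_equal(a3$ss[a3$term == "A"], 4.234496124, tolerance = 1e-8)
  expect_equal(a3$ss[a3$term == "B"], 11.408333333, tolerance = 1e-8)
})

test_that("degrees of freedom always sum to n - 1; SS are non-negative", {
  d <- worked_anova_data()
  for (type in 1:3) {
    a <- two_way_anova(d, "y", "A", "B", ss_type = type)
    expect_equal(sum(a$df), nrow(d) - 1)
    expect_true(all(a$ss >= 0))
    expect_true(all(is.na(a$p) | (a$p >= 0 & a$p <= 1)))
  }
  # balanced design: Type II equals the sequential decomposition and the
  # term SS sum to the total SS
  set.seed(8)
  b <- data.frame(A = gl(2, 6), B = gl(3, 2, 12), y = rnorm(12))
  a1 <- two_way_anova(b, "y", "A", "B", ss_type = 1)
  a2 <- two_way_anova(b, "y", "A", "B", ss_type = 2)
  expect_equal(a1$ss, a2$ss, tolerance = 1e-10)
  expect_equal(sum(a2$ss), sum((b$y - mean(b$y))^2), tolerance = 1e-10)
})

test_that("with one factor constant, F equals the squared two-sample t", {
  set.seed(13)
  d <- data.frame(A = rep(c("g1", "g2"), each = 8), y = rnorm(16))
  a <- two_way_anova(d, "y", "A", factor_b = NULL)
  tt <- t.test(y ~ A, data = d, var.equal = TRUE)
  expect_equal(a$statistic[a$term == "A"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$term == "A"], tt$p.value, tolerance = 1e-10)
})

test_that("empty cells and constant responses are reported, not crashed", {
  d <- worked_anova_data()
  d <- d[!(d$A == "a3" & d$B == "m"), ]
  expect_error(two_way_anova(d, "y", "A", "B"), "empty.*interaction = FALSE")
  a <- two_way_anova(d, "y", "A", "B", interaction = FALSE)
  expect_true(all(c("A", "B", "residual") %in% a$term))

  dc <- worked_anova_data(); dc$y <- 5
  expect_warning(a0 <- two_way_anova(dc, "y", "A", "B"), "constant response")
  expect_equal(sum(a0$ss), 0, tolerance = 1e-20)
  expect_true(all(is.nan(a0$statistic[a0$term != "residual"])))
})

test_that("ANOVA agrees with the reference implementation on 50 random designs", {
  skip_if_not_installed("car")
  set.seed(77)
  for (rep in 1:50) {
    ka <- sample(2:4, 1); kb <- 2
    repeat {
      n <- sample(12:30, 1)
      A <- factor(sample(letters[1:ka], n, replace = TRUE))
      B <- factor(sample(c("f", "m"), n, replace = TRUE))
      if (all(table(A, B) >= 1) && nlevels(droplevels(A)) == ka) break
    }
    y <- rnorm(n, mean = as.integer(A) + 0.5 * as.integer(B))
    d <- data.frame(A = A, B = B, y = y)
    mine <- two_way_anova(d, "y", "A", "B", ss_type = 2)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    ref <- car::Anova(lm(y ~ A * B, data = d), type = 2)
    options(old)
    expect_equal(mine$ss[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
    expect_equal(mine$statistic[1:3], ref$`F value`[1:3], tolerance = 1e-8)
    expect_equal(mine$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-8)
  }
})

test_that("Tukey-Kramer agrees with the reference implementation on 50 designs", {
  set.seed(99)
  for (rep in 1:50) {
    k <- sample(3:5, 1)
    n <- sample(3:9, k, replace = TRUE)
    g <- factor(rep(letters[1:k], n))
    y <- rnorm(sum(n), mean = rep(runif(k, 0, 3), n))
    mine <- tukey_kramer(y, g)
    ref <- TukeyHSD(aov(y ~ g))$g
    expect_equal(mine$pairs$diff, unname(ref[, "diff"]), tolerance = 1e-8)
    expect_equal(mine$pairs$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  }
})

test_that("two-group Tukey reduces to the pooled-variance t-test (q = sqrt(2) |t|)", {
  set.seed(5)
  y <- c(rnorm(7, 10), rnorm(5, 11))
  g <- rep(c("a", "b"), c(7, 5))
  tk <- tukey_kramer(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$pairs$q, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("identical samples share one letter; zero-variance separates by mean", {
  y <- rep(c(4, 7, 9), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  tk <- tukey_kramer(rep(5, 9), g)
  expect_equal(tk$pairs$p_adj, rep(1, 3))
  expect_equal(unname(tk$letters), rep("a", 3))

  tk2 <- tukey_kramer(rep(c(4, 7, 9), each = 3), g) # zero within-variance
  expect_true(all(tk2$pairs$p_adj == 0))
  expect_equal(length(unique(tk2$letters)), 3)

  expect_error(tukey_kramer(1:3, rep("a", 3)), "2 groups")
  expect_error(tukey_kramer(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("letter displays are correct for every significance pattern up to k = 5", {
  for (k in 2:5) {
    pairs <- utils::combn(k, 2)
    for (mask in 0:(2^ncol(pairs) - 1)) {
      sig <- matrix(FALSE, k, k)
      bits <- as.logical(bitwAnd(mask, 2^(seq_len(ncol(pairs)) - 1)))
      for (j in which(bits)) {
        sig[pairs[1, j], pairs[2, j]] <- TRUE
        sig[pairs[2, j], pairs[1, j]] <- TRUE
      }
      lets <- compact_letters(sig)
      share <- function(i, j) {
        li <- strsplit(lets[i], "")[[1]]
        any(li %in% strsplit(lets[j], "")[[1]])
      }
      for (j in seq_len(ncol(pairs))) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        expect_identical(share(i1, i2), !sig[i1, i2],
                         label = sprintf("k=%d mask=%d pair=(%d,%d)",
                                         k, mask, i1, i2))
      }
    }
  }
})

test_that("simulated rump-length groups reproduce the calibration letter pattern", {
  # biotype means 48.00/49.88/48.21 cm, CV 5.91%, original sizes 57/20/18:
  # the Negro-Callejon difference is the detectable one; Negro-Atigrado is
  # not. Checked in the large-sample limit of the standard errors by
  # averaging the adjusted p over replicates.
  means <- c(NEGRO = 48.00, CALLEJON = 49.88, ATIGRADO = 48.21)
  n <- c(NEGRO = 57, CALLEJON = 20, ATIGRADO = 18)
  set.seed(2023)
  p_nc <- p_na <- numeric(40)
  for (r in 1:40) {
    g <- factor(rep(names(n), n), levels = names(n))
    y <- rnorm(sum(n), mean = rep(means, n), sd = rep(0.0591 * means, n))
    tk <- tukey_kramer(y, g)
    p_nc[r] <- tk$pairs$p_adj[tk$pairs$group1 == "NEGRO" &
                                tk$pairs$group2 == "CALLEJON"]
    p_na[r] <- tk$pairs$p_adj[tk$pairs$group1 == "NEGRO" &
                                tk$pairs$group2 == "ATIGRADO"]
  }
  expect_lt(median(p_nc), 0.05) # borderline by design, but detected typically
  expect_gt(median(p_na), 0.05)
})

test_that("Pearson matrix reproduces hand-computed and exact cases", {
  x <- 1:10
  pm <- pearson_matrix(data.frame(x = x, y = 2 * x + 1))
  expect_equal(pm$r["x", "y"], 1)
  expect_equal(pm$p["x", "y"], 0)

  pm2 <- pearson_matrix(data.frame(x = c(1, 2, 3), y = c(1, 3, 2)))
  expect_equal(pm2$r["x", "y"], 0.5, tolerance = 1e-12)

  # structural invariants
  set.seed(3)
  m <- as.data.frame(matrix(rnorm(60), ncol = 3))
  pm3 <- pearson_matrix(m)
  expect_equal(diag(pm3$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pm3$r, t(pm3$r))
  expect_true(all(abs(pm3$r) <= 1))
  # p from the t transform matches cor.test
  ct <- cor.test(m[[1]], m[[2]])
  expect_equal(pm3$p[1, 2], ct$p.value, tolerance = 1e-10)

  m$z <- 1
  expect_warning(pm4 <- pearson_matrix(m), "zero-variance")
  expect_true(all(is.na(pm4$r["z", c("V1", "V2", "V3")])))

  pm5 <- pearson_matrix(m[, 1:3], adjust = "bonferroni")
  expect_equal(pm5$p[1, 2], min(1, 3 * pm3$p[1, 2]), tolerance = 1e-12)
})

test_that("assumption checks calibrate to the nominal level and detect heteroscedasticity", {
  set.seed(31)
  rej_norm <- rej_homo <- logical(200)
  for (r in 1:200) {
    y <- rnorm(45)
    g <- gl(3, 15)
    ck <- assumption_checks(y, g)
    rej_norm[r] <- any(ck$normality$p < 0.05)
    rej_homo[r] <- ck$homoscedasticity$p < 0.05
  }
  # three independent Shapiro tests: familywise type-I near 1-(0.95)^3
  expect_gt(mean(rej_norm), 0.05)
  expect_lt(mean(rej_norm), 0.30)
  expect_lt(mean(rej_homo), 0.12)

  # power: one group with 10x the SD is caught at moderate n
  set.seed(32)
  y <- c(rnorm(60), rnorm(60, sd = 10), rnorm(60))
  ck <- assumption_checks(y, gl(3, 60))
  expect_lt(ck$homoscedasticity$p, 1e-6)

  # degenerate groups flagged, not crashed
  ck2 <- assumption_checks(c(rep(1, 5), rnorm(5)), gl(2, 5))
  expect_equal(ck2$normality$note[1], "constant sample")
})
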