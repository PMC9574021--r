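test_that("pain indices follow their VAS-difference definitions", {
  vt <- data.frame(
    participant_id = rep(c("p1", "p2", "p3"), each = 4),
    group = "young_male",
    condition = rep(c("HF-HS", "LF-HS", "HF-LS", "LF-LS"), 3),
    mean_vas = c(
      70, 55, 40, 30, # reduction 15, enhancement 10
      50, 50, 50, 50, # both 0
      50, 60, 45, 40  # reduction -10 (negative allowed), enhancement 5
    )
  )
  idx <- pain_indices(vt)
  expect_equal(idx$reduction_index, c(15, 0, -10))
  expect_equal(idx$enhancement_index, c(10, 0, 5))
  expect_error(pain_indices(vt[-1, ]), "lacks condition")
})

# textbook sums-of-squares oracle for a balanced two-way between design
ss_oracle_2x2 <- function(y, a, b) {
  N <- length(y)
  gm <- mean(y)
  ss_a <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(a, b), mean)
  nc <- tapply(y, list(a, b), length)
  ss_cells <- sum(nc * (cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, a, b))^2)
  df_e <- N - length(cellm)
  list(
    F_a = (ss_a / 1) / (ss_e / df_e),
    F_b = (ss_b / 1) / (ss_e / df_e),
    F_ab = (ss_ab / 1) / (ss_e / df_e),
    df_e = df_e
  )
}

test_that("factorial ANOVA matches a hand sums-of-squares decomposition", {
  set.seed(3)
  d <- data.frame(
    participant_id = 1:24,
    y = rnorm(24, rep(c(0, 1, 0.5, 2), each = 6)),
    a = rep(c("x", "y"), each = 12),
    b = rep(rep(c("u", "v"), each = 6), 2)
  )
  res <- factorial_anova(d, "y", between = c("a", "b"))
  orc <- ss_oracle_2x2(d$y, d$a, d$b)
  expect_equal(res$value[res$term == "a"], orc$F_a, tolerance = 1e-10)
  expect_equal(res$value[res$term == "b"], orc$F_b, tolerance = 1e-10)
  expect_equal(res$value[res$term == "a:b"], orc$F_ab, tolerance = 1e-10)
  expect_true(all(res$df2 == orc$df_e))
})

test_that("identical groups give a zero F for the group effect", {
  d <- data.frame(
    participant_id = 1:10,
    y = rep(c(1, 2, 3, 4, 5), 2),
    g = rep(c("a", "b"), each = 5)
  )
  res <- factorial_anova(d, "y", between = "g")
  expect_equal(res$value, 0)
  expect_error(
    factorial_anova(data.frame(participant_id = 1:4, y = 1:4, g = "a"), "y", "g"),
    "fewer than 2"
  )
})

test_that("the pooled error model reproduces the study's denominator df", {
  # 60 participants x 2 within-levels, 2x2 between factors: df2 = 120 - 8 = 112
  set.seed(4)
  d <- expand.grid(
    participant_id = sprintf("p%02d", 1:60),
    condition = c("matched", "mismatched")
  )
  d$age <- rep(rep(c("young", "elderly"), each = 30), 2)
  d$sex <- rep(rep(c("male", "female"), each = 15, times = 2), 2)
  d$y <- rnorm(nrow(d))
  pooled <- factorial_anova(d, "y",
    between = c("age", "sex"), within = "condition",
    error_model = "pooled"
  )
  expect_true(all(pooled$df2 == 112))
  expect_setequal(
    pooled$term,
    c(
      "age", "sex", "condition", "age:sex", "age:condition",
      "sex:condition", "age:sex:condition"
    )
  )
  # mixed model nests condition in a subject stratum
  mixed <- factorial_anova(d, "y",
    between = c("age", "sex"), within = "condition",
    error_model = "mixed"
  )
  expect_equal(mixed$df2[mixed$term == "age"], 56)
  expect_equal(mixed$df2[mixed$term == "condition"], 56)
  # two-way between ANOVA on a 60-participant index table: df2 = 56
  d2 <- d[d$condition == "matched", ]
  twoway <- factorial_anova(d2, "y", between = c("age", "sex"))
  expect_true(all(twoway$df2 == 56))
})

test_that("Bonferroni post hoc multiplies raw p by the comparison count", {
  set.seed(5)
  x <- rnorm(40)
  g <- rep(letters[1:4], each = 10)
  res <- bonferroni_posthoc(x, g)
  expect_equal(nrow(res), 6)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 6))
  # cross-check raw p against pairwise.t.test with pooled SD
  ptt <- pairwise.t.test(x, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(
    res$p_raw[res$term == "a vs b"], ptt$p.value["b", "a"],
    tolerance = 1e-12
  )
  # identical groups: t = 0, raw p = 1, adjusted capped at 1
  res0 <- bonferroni_posthoc(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$value, 0)
  expect_equal(res0$p_adjusted, 1)
})

test_that("Holm adjustment reproduces the printed correlation family", {
  p <- c(0.006, 0.023, 0.023, 0.329)
  adj <- holm_adjust(p)
  expect_equal(adj[1], 0.024)
  expect_equal(adj[2], 0.069)
  expect_equal(adj[3], 0.069) # monotone variant ties up
  expect_equal(adj[4], 0.329)
  # matches R's reference implementation
  expect_equal(adj, p.adjust(p, "holm"))
  # raw-multiplier variant reproduces the non-monotone arithmetic
  raw <- holm_adjust(p, "raw-multiplier")
  expect_equal(raw, c(0.024, 0.069, 0.046, 0.329))
  # single-element family: adjusted equals raw
  expect_equal(holm_adjust(0.2), 0.2)
})

test_that("Holm ordering properties hold on random families", {
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    h <- holm_adjust(p)
    b <- pmin(1, p * length(p))
    expect_true(all(h >= p - 1e-15))
    expect_true(all(b >= h - 1e-15)) # Bonferroni >= Holm >= raw
    expect_true(all(h <= 1))
    o <- order(p)
    expect_true(all(diff(h[o]) >= -1e-15)) # monotone in raw-p order
    expect_equal(h, p.adjust(p, "holm"))
  }
})

test_that("per-group Pearson correlations carry Holm-adjusted p values", {
  set.seed(7)
  g <- rep(c("a", "b"), each = 20)
  x <- rnorm(40)
  y <- x * rep(c(0.9, 0), each = 20) + rnorm(40, 0, 0.5)
  res <- pearson_with_holm(x, y, g)
  expect_equal(res$p_adjusted, holm_adjust(res$p_raw))
  ct <- cor.test(x[1:20], y[1:20])
  expect_equal(res$value[1], unname(ct$estimate))
  expect_equal(res$p_raw[1], ct$p.value)
  # exact linear relation gives r = 1
  res1 <- pearson_with_holm(1:10, 2 * (1:10), rep("a", 10))
  expect_equal(res1$value, 1)
  expect_error(pearson_with_holm(rep(1, 10), rnorm(10), rep("a", 10)), "variance")
})

test_that("forced-entry regression matches the normal-equations oracle", {
  # small integer system solvable by hand via the normal equations
  y <- c(2, 4, 5, 4, 7)
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- c(0, 1, 0, 1, 1)
  Z <- scale(cbind(x1, x2))
  zy <- as.numeric(scale(y))
  beta_oracle <- solve(crossprod(Z), crossprod(Z, zy))
  res <- regression_forced(y, data.frame(x1 = x1, x2 = x2))
  b <- res[res$statistic == "beta", ]
  expect_equal(b$value, as.numeric(beta_oracle), tolerance = 1e-10)
  # R^2 equals squared correlation of fit
  fit <- lm(y ~ x1 + x2)
  expect_equal(
    res$effect_measure[res$term == "model"], summary(fit)$r.squared,
    tolerance = 1e-12
  )
  expect_equal(res$df1[res$term == "model"], 2)
  expect_equal(res$df2[res$term == "model"], 2)
})

test_that("regression handles perfect fits, null fits and collinearity", {
  set.seed(8)
  x1 <- rnorm(50)
  x2 <- rnorm(50)
  res <- suppressWarnings(regression_forced(x1, data.frame(x1 = x1, x2 = x2)))
  b <- res[res$statistic == "beta", ]
  expect_equal(b$value[b$term == "x1"], 1, tolerance = 1e-6)
  expect_gt(res$effect_measure[res$term == "model"], 1 - 1e-10)
  # independent response: R^2 near zero at large n
  set.seed(9)
  n <- 1000
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  res0 <- regression_forced(rnorm(n), X)
  expect_lt(res0$effect_measure[res0$term == "model"], 0.05)
  expect_error(
    regression_forced(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
    "collinear"
  )
  expect_error(regression_forced(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3))), "need n")
})

test_that("stepwise selection keeps real predictors and drops noise", {
  set.seed(10)
  hits <- 0
  empty <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    n <- 60
    x <- data.frame(
      a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n)
    )
    y_sig <- 0.9 * scale(x$a)[, 1] + sqrt(1 - 0.81) * rnorm(n)
    sel <- attr(regression_stepwise(y_sig, x, alpha_enter = 0.01), "selected")
    if (identical(sel, "a")) hits <- hits + 1
    y_noise <- rnorm(n)
    sel0 <- attr(regression_stepwise(y_noise, x, alpha_enter = 0.01), "selected")
    if (length(sel0) == 0) empty <- empty + 1
  }
  expect_gt(hits / n_rep, 0.95) # r = 0.9 predictor essentially always found
  expect_gte(empty / n_rep, 0.95) # family-wise entry rate bounded by 4 x 0.01
})

test_that("a degenerate entry threshold reduces stepwise to forced entry", {
  set.seed(11)
  x <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  y <- rnorm(30)
  step_all <- suppressWarnings(regression_stepwise(y, x, alpha_enter = 1.0))
  expect_setequal(attr(step_all, "selected"), c("a", "b", "c"))
  forced <- regression_forced(y, x)
  expect_equal(
    sort(step_all$value[step_all$statistic == "beta"]),
    sort(forced$value[forced$statistic == "beta"]),
    tolerance = 1e-12
  )
})

# brute-force U statistic: count pairs where x beats y (ties count 1/2)
u_oracle <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("Mann-Whitney U matches the pair-count definition and wilcox.test", {
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:10, sample(3:8, 1), replace = TRUE)
    y <- sample(1:10, sample(3:8, 1), replace = TRUE)
    res <- mann_whitney_r(x, y)
    expect_equal(res$value, u_oracle(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(res$p_raw, wt$p.value, tolerance = 1e-12)
  }
  # complete separation: U = 0 for the lower sample
  expect_equal(mann_whitney_r(c(1, 2, 3), c(4, 5, 6))$value, 0)
  # identical samples: degenerate, p = 1, r = 0
  res0 <- mann_whitney_r(rep(2, 5), rep(2, 5))
  expect_equal(res0$p_raw, 1)
  expect_equal(res0$effect_measure, 0)
  expect_error(mann_whitney_r(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney effect size r is Z over sqrt(N) with directional sign", {
  set.seed(13)
  x <- rnorm(15, 0)
  y <- rnorm(15, 2)
  res <- mann_whitney_r(x, y)
  expect_lt(res$effect_measure, 0) # first sample ranks lower
  expect_true(abs(res$effect_measure) <= 1)
  expect_equal(
    res$effect_measure,
    -qnorm(res$p_raw / 2) / sqrt(30) * sign(res$value - 15 * 15 / 2),
    tolerance = 1e-10
  )
})

test_that("assumption checks report KS, Brown-Forsythe and Mauchly correctly", {
  set.seed(14)
  x <- rnorm(60)
  g <- rep(letters[1:3], each = 20)
  res <- assumption_checks(x, g, within_matrix = matrix(rnorm(40), 20, 2))
  expect_equal(sum(grepl("KS normality", res$term)), 3)
  bf <- res[res$term == "Brown-Forsythe homogeneity", ]
  # oracle: one-way ANOVA on absolute deviations from group medians
  med <- tapply(x, g, median)
  z <- abs(x - med[g])
  orc <- anova(lm(z ~ g))
  expect_equal(bf$value, orc[1, "F value"], tolerance = 1e-12)
  expect_equal(bf$p_raw, orc[1, "Pr(>F)"], tolerance = 1e-12)
  # a 2-level within factor has no sphericity to test
  mau <- res[res$term == "Mauchly sphericity", ]
  expect_true(is.na(mau$value))
  expect_match(mau$adjustment, "not-applicable")
  # equal spread around group medians: F near 0
  x_eq <- c(1, 2, 3, 11, 12, 13)
  res_eq <- assumption_checks(x_eq, rep(c("a", "b"), each = 3))
  expect_equal(res_eq$value[res_eq$term == "Brown-Forsythe homogeneity"], 0)
})

test_that("Brown-Forsythe agrees with car::leveneTest(center = median)", {
  skip_if_not_installed("car")
  set.seed(15)
  x <- rnorm(45, sd = rep(c(1, 2, 3), each = 15))
  g <- factor(rep(letters[1:3], each = 15))
  res <- assumption_checks(x, g)
  lev <- car::leveneTest(x, g, center = median)
  bf <- res[res$term == "Brown-Forsythe homogeneity", ]
  expect_equal(bf$value, lev[1, "F value"], tolerance = 1e-10)
  expect_equal(bf$p_raw, lev[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("Mauchly reports W and p for a 3-level within factor", {
  set.seed(16)
  Y <- matrix(rnorm(90), 30, 3)
  res <- assumption_checks(rnorm(30), rep("a", 30), within_matrix = Y)
  mau <- res[res$term == "Mauchly sphericity", ]
  expect_true(is.finite(mau$value))
  expect_true(mau$p_raw >= 0 && mau$p_raw <= 1)
})
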