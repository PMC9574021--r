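stat_row <- function(analysis, term, kind, value, df1 = NA, df2 = NA,
                     p_raw = NA, p_adj = NA, method = NA_character_,
                     extra = NA) {
  data.frame(
    analysis = analysis, term = term, statistic = kind, value = value,
    df1 = df1, df2 = df2, p_raw = p_raw, p_adjusted = p_adj,
    adjustment = method, effect_measure = extra, stringsAsFactors = FALSE
  )
}

#' Pain reduction and enhancement indices
#'
#' The placebo (pain-reduction) index is the drop in reported pain when the
#' high-intensity shock follows the safe cue instead of its trained cue:
#' `VAS(HF-HS) - VAS(LF-HS)`. The nocebo (pain-enhancement) index is the rise
#' in reported pain when the low-intensity shock follows the threat cue:
#' `VAS(HF-LS) - VAS(LF-LS)`. Indices may be negative; no clipping is applied.
#'
#' @param vas_table Data frame with columns `participant_id`, `group`,
#'   `condition` (all four condition levels per participant) and `mean_vas`.
#' @return Data frame: `participant_id`, `group`, `reduction_index`,
#'   `enhancement_index`.
#' @export
#' @examples
#' vt <- data.frame(
#'   participant_id = "p1", group = "young_male",
#'   condition = c("HF-HS", "LF-HS", "HF-LS", "LF-LS"),
#'   mean_vas = c(70, 55, 40, 30)
#' )
#' pain_indices(vt) # reduction 15, enhancement 10
pain_indices <- function(vas_table) {
  stopifnot(all(c("participant_id", "condition", "mean_vas") %in% names(vas_table)))
  ids <- unique(vas_table$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- vas_table[vas_table$participant_id == id, ]
    v <- setNames(sub$mean_vas, as.character(sub$condition))
    missing <- setdiff(CONDITION_LEVELS, names(v))
    if (length(missing)) {
      stop_invalid(
        "participant %s lacks condition(s): %s", id,
        paste(missing, collapse = ", ")
      )
    }
    data.frame(
      participant_id = id,
      group = if ("group" %in% names(sub)) sub$group[1] else NA,
      reduction_index = unname(v["HF-HS"] - v["LF-HS"]),
      enhancement_index = unname(v["HF-LS"] - v["LF-LS"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Factorial ANOVA with pooled or mixed error model
#'
#' Fits a full-factorial ANOVA for up to two between-subject factors and an
#' optional within-subject (repeated) factor, returning F, degrees of freedom
#' and p for every main effect and interaction.
#'
#' `error_model = "pooled"` treats all factors as between-subjects (a single
#' residual error stratum); on a 4-group x 15-participant x 2-condition design
#' this yields denominator df 112, the df pattern printed by SPSS-style
#' analyses pooling the repeated factor. `error_model = "mixed"` nests the
#' within factor in a subject error stratum (the textbook repeated-measures
#' model) and is the recommended model when a within factor is present.
#'
#' @param data Data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param between Character vector of between-subject factor names.
#' @param within Optional within-subject factor name.
#' @param subject Subject identifier column (required for the mixed model).
#' @param error_model `"pooled"` or `"mixed"`.
#' @param analysis Label written to the `analysis` column of the result.
#' @return Data frame of `StatResult` rows (`analysis`, `term`, `statistic`,
#'   `value`, `df1`, `df2`, `p_raw`, ...).
#' @export
factorial_anova <- function(data, dv, between, within = NULL,
                            subject = "participant_id",
                            error_model = c("pooled", "mixed"),
                            analysis = "anova") {
  error_model <- match.arg(error_model)
  factors <- c(between, within)
  for (f in factors) {
    data[[f]] <- droplevels(factor(data[[f]]))
    if (nlevels(data[[f]]) < 2) {
      stop_invalid("factor `%s` has fewer than 2 levels", f)
    }
  }
  rhs <- paste(factors, collapse = " * ")
  if (error_model == "mixed" && !is.null(within)) {
    data[[subject]] <- factor(data[[subject]])
    form <- stats::as.formula(paste(
      dv, "~", rhs, "+ Error(", subject, "/", within, ")"
    ))
    fit <- aov(form, data = data)
    strata <- summary(fit)
    rows <- list()
    for (s in strata) {
      tab <- s[[1]]
      terms <- trimws(rownames(tab))
      res <- terms == "Residuals"
      df2 <- tab[res, "Df"]
      for (i in which(!res)) {
        rows[[length(rows) + 1L]] <- stat_row(
          analysis, terms[i], "F", tab[i, "F value"],
          df1 = tab[i, "Df"], df2 = df2, p_raw = tab[i, "Pr(>F)"]
        )
      }
    }
    out <- do.call(rbind, rows)
  } else {
    form <- stats::as.formula(paste(dv, "~", rhs))
    tab <- anova(lm(form, data = data))
    terms <- rownames(tab)
    res <- terms == "Residuals"
    df2 <- tab[res, "Df"]
    rows <- lapply(which(!res), function(i) {
      stat_row(
        analysis, terms[i], "F", tab[i, "F value"],
        df1 = tab[i, "Df"], df2 = df2, p_raw = tab[i, "Pr(>F)"]
      )
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Pairwise t tests between group means using the pooled within-group error
#' variance from the omnibus one-way ANOVA (the SPSS-style Bonferroni post
#' hoc), with each raw p multiplied by the number of comparisons and capped
#' at 1.
#'
#' @param x Numeric response vector.
#' @param g Grouping factor.
#' @param comparisons Optional list of length-2 character vectors naming the
#'   group pairs to test; defaults to all pairs.
#' @param analysis Label written to the `analysis` column of the result.
#' @return `StatResult` data frame, one row per comparison.
#' @export
bonferroni_posthoc <- function(x, g, comparisons = NULL,
                               analysis = "bonferroni_posthoc") {
  g <- droplevels(factor(g))
  if (any(table(g) == 0)) stop_invalid("empty group in post hoc comparison")
  lev <- levels(g)
  if (length(lev) < 2) stop_invalid("need at least two groups")
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lev, 2, simplify = FALSE)
  }
  ns <- table(g)
  means <- tapply(x, g, mean)
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / (length(x) - length(lev))
  df <- length(x) - length(lev)
  m <- length(comparisons)
  rows <- lapply(comparisons, function(pr) {
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tv <- if (se == 0) 0 else (means[[pr[1]]] - means[[pr[2]]]) / se
    p <- 2 * pt(-abs(tv), df)
    stat_row(
      analysis, paste(pr, collapse = " vs "), "t", tv,
      df1 = df, p_raw = p, p_adj = min(1, p * m), method = "bonferroni"
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm step-down p-value adjustment
#'
#' Standard monotone Holm adjustment: with raw p-values sorted ascending,
#' `p_adj[i] = max_{j <= i} (m - j + 1) * p[j]`, capped at 1. The
#' `"raw-multiplier"` variant omits the cumulative-maximum (monotonicity)
#' step, i.e. `p_adj = (m - rank + 1) * p` with ties broken by input order —
#' the arithmetic some statistics packages print for tied raw p-values.
#'
#' @param p Numeric vector of raw p-values.
#' @param variant `"standard"` (monotone, default) or `"raw-multiplier"`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.006, 0.023, 0.023, 0.329)) # 0.024 0.069 0.069 0.329
#' holm_adjust(c(0.006, 0.023, 0.023, 0.329), "raw-multiplier")
holm_adjust <- function(p, variant = c("standard", "raw-multiplier")) {
  variant <- match.arg(variant)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  mult <- (m - seq_len(m) + 1) * p[o]
  adj <- if (variant == "standard") cummax(mult) else mult
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

#' Per-group Pearson correlations with Holm correction
#'
#' Computes a Pearson correlation (two-sided) between `x` and `y` within each
#' level of `g` and adjusts the family of per-group p-values with
#' [holm_adjust()].
#'
#' @param x,y Numeric vectors.
#' @param g Grouping factor.
#' @param variant Holm variant; see [holm_adjust()].
#' @param analysis Label written to the `analysis` column of the result.
#' @return `StatResult` data frame, one row per group, ordered by the levels
#'   of `g`, with `value` = r and `df1` = n - 2.
#' @export
pearson_with_holm <- function(x, y, g, variant = "standard",
                              analysis = "pearson") {
  g <- droplevels(factor(g))
  rows <- lapply(levels(g), function(lev) {
    xi <- x[g == lev]
    yi <- y[g == lev]
    keep <- complete.cases(xi, yi)
    xi <- xi[keep]; yi <- yi[keep]
    if (length(xi) < 3) stop_invalid("group %s has n < 3", lev)
    if (sd(xi) == 0 || sd(yi) == 0) {
      stop_invalid("zero variance in group %s", lev)
    }
    ct <- cor.test(xi, yi)
    stat_row(
      analysis, lev, "r", unname(ct$estimate),
      df1 = unname(ct$parameter), p_raw = ct$p.value
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_adjust(out$p_raw, variant)
  out$adjustment <- paste0("holm", if (variant != "standard") " (raw-multiplier)" else "")
  rownames(out) <- NULL
  out
}

# z-score helper; constant columns raise an error upstream.
zscore <- function(x) (x - mean(x)) / sd(x)

# two-level factors/characters/logicals become 0/1 columns
coerce_predictors <- function(predictors) {
  X <- as.data.frame(predictors)
  for (j in names(X)) {
    if (is.factor(X[[j]]) || is.character(X[[j]]) || is.logical(X[[j]])) {
      f <- droplevels(factor(X[[j]]))
      if (nlevels(f) != 2) stop_invalid("predictor `%s` is not numeric or binary", j)
      X[[j]] <- as.numeric(f) - 1
    }
  }
  X
}

#' Forced-entry multiple regression with standardized coefficients
#'
#' Fits an ordinary least-squares regression of `y` on all columns of
#' `predictors` after z-scoring response and predictors (so coefficients are
#' standardized betas), and reports the overall F, R-squared and
#' per-coefficient beta and p.
#'
#' @param y Numeric response.
#' @param predictors Data frame (or matrix) of numeric predictors; factors
#'   with two levels are converted to 0/1.
#' @param analysis Label written to the `analysis` column of the result.
#' @return `StatResult` data frame: one `model` row (F, df1, df2, p, with
#'   R-squared in `effect_measure`) followed by one `beta` row per predictor.
#' @export
regression_forced <- function(y, predictors, analysis = "regression_forced") {
  X <- coerce_predictors(predictors)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop_invalid("need n > number of predictors + 1")
  for (j in names(X)) {
    if (sd(X[[j]]) == 0) stop_invalid("predictor `%s` has zero variance", j)
  }
  cx <- cor(X)
  diag(cx) <- 0
  if (any(abs(cx) > 1 - 1e-10)) {
    bad <- which(abs(cx) == max(abs(cx)), arr.ind = TRUE)[1, ]
    stop_invalid(
      "predictors `%s` and `%s` are collinear",
      names(X)[bad[1]], names(X)[bad[2]]
    )
  }
  Z <- as.data.frame(lapply(X, zscore))
  dat <- cbind(.y = zscore(y), Z)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p_model <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  rows <- list(stat_row(
    analysis, "model", "F", unname(fstat[1]),
    df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p_raw = unname(p_model), extra = sm$r.squared
  ))
  ct <- sm$coefficients
  for (j in names(Z)) {
    rows[[length(rows) + 1L]] <- stat_row(
      analysis, j, "beta", ct[j, "Estimate"],
      df1 = unname(fstat[3]), p_raw = ct[j, "Pr(>|t|)"]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise multiple regression by p-value
#'
#' Forward selection with backward pruning: repeatedly add the candidate
#' predictor with the smallest entry p-value below `alpha_enter`; after each
#' addition, drop any included predictor whose p-value has risen above
#' `alpha_remove`; stop when the model no longer changes. The final model is
#' reported via [regression_forced()] (standardized betas). An empty final
#' model yields a zero-row result.
#'
#' @inheritParams regression_forced
#' @param alpha_enter p-value threshold to enter (default 0.05).
#' @param alpha_remove Threshold to remove (defaults to `alpha_enter`).
#' @param analysis Label written to the `analysis` column of the result.
#' @return `StatResult` data frame for the selected model; the selected
#'   predictor names are in `attr(, "selected")`.
#' @export
regression_stepwise <- function(y, predictors, alpha_enter = 0.05,
                                alpha_remove = alpha_enter,
                                analysis = "regression_stepwise") {
  X <- coerce_predictors(predictors)
  included <- character(0)
  repeat {
    changed <- FALSE
    candidates <- setdiff(names(X), included)
    if (length(candidates)) {
      ps <- vapply(candidates, function(j) {
        fit <- lm(y ~ ., data = cbind(
          data.frame(y = y),
          X[, c(included, j), drop = FALSE]
        ))
        summary(fit)$coefficients[j, "Pr(>|t|)"]
      }, numeric(1))
      if (min(ps) < alpha_enter) {
        included <- c(included, candidates[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(included) > 1) {
      fit <- lm(y ~ ., data = cbind(
        data.frame(y = y),
        X[, included, drop = FALSE]
      ))
      ps <- summary(fit)$coefficients[included, "Pr(>|t|)"]
      worst <- which.max(ps)
      if (ps[worst] > alpha_remove) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(included)) {
    out <- stat_row(analysis, "none", "none", NA_real_)[0, ]
    attr(out, "selected") <- character(0)
    return(out)
  }
  out <- regression_forced(y, X[, included, drop = FALSE], analysis = analysis)
  attr(out, "selected") <- included
  out
}

#' Mann-Whitney U test with rank-based effect size r
#'
#' Two-sided Mann-Whitney U test using the normal approximation with tie
#' correction and no continuity correction (the convention of SPSS-style
#' output), reporting the effect size \eqn{r = Z/\sqrt{n_1+n_2}} whose sign
#' follows the direction of the first sample's mean rank. If every value is
#' tied across both samples the test is degenerate: p = 1, r = 0.
#'
#' @param x,y Numeric samples.
#' @param analysis Label written to the `analysis` column of the result.
#' @return One `StatResult` row with `value` = U (for `x`), `p_raw`, and r in
#'   `effect_measure`.
#' @export
mann_whitney_r <- function(x, y, analysis = "mann_whitney") {
  if (!length(x) || !length(y)) stop_invalid("both samples must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r_all <- rank(c(x, y))
  R1 <- sum(r_all[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sig2 <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (U1 - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  stat_row(
    analysis, "x vs y", "U", U1,
    df1 = NA, p_raw = p, extra = z / sqrt(N)
  )
}

#' Distributional assumption checks
#'
#' Normality per cell (Lilliefors-corrected Kolmogorov-Smirnov by default,
#' i.e. the estimated-parameter KS check of SPSS-style pipelines, or the
#' plain KS test against a fitted normal), Brown-Forsythe homogeneity of
#' variance (one-way ANOVA on absolute deviations from the group medians),
#' and Mauchly's test of sphericity for a within factor (reported as
#' not-applicable when the factor has fewer than three levels, where
#' sphericity is trivially satisfied).
#'
#' @param x Numeric response.
#' @param g Grouping factor (cells).
#' @param within_matrix Optional subjects x levels matrix of a within-subject
#'   factor for Mauchly's test.
#' @param normality `"lilliefors"` or `"ks"`.
#' @param analysis Label written to the `analysis` column of the result.
#' @return `StatResult` data frame: one `KS` row per cell, one
#'   `Brown-Forsythe` row, and one `Mauchly` row if `within_matrix` is given.
#' @export
assumption_checks <- function(x, g, within_matrix = NULL,
                              normality = c("lilliefors", "ks"),
                              analysis = "assumptions") {
  normality <- match.arg(normality)
  g <- droplevels(factor(g))
  rows <- list()
  for (lev in levels(g)) {
    xi <- x[g == lev]
    if (length(xi) < 4 || sd(xi) == 0) {
      rows[[length(rows) + 1L]] <- stat_row(
        analysis, paste0("KS normality: ", lev), "D", NA,
        method = "not-applicable (n too small or constant)"
      )
      next
    }
    tst <- if (normality == "lilliefors") {
      nortest::lillie.test(xi)
    } else {
      suppressWarnings(ks.test(xi, "pnorm", mean(xi), sd(xi)))
    }
    rows[[length(rows) + 1L]] <- stat_row(
      analysis, paste0("KS normality: ", lev), "D",
      unname(tst$statistic), p_raw = tst$p.value, method = normality
    )
  }
  # Brown-Forsythe: ANOVA on |x - median(group)|
  if (nlevels(g) >= 2 && all(table(g) >= 2)) {
    med <- tapply(x, g, median)
    z <- abs(x - med[as.character(g)])
    tab <- anova(lm(z ~ g))
    rows[[length(rows) + 1L]] <- stat_row(
      analysis, "Brown-Forsythe homogeneity", "F", tab[1, "F value"],
      df1 = tab[1, "Df"], df2 = tab[2, "Df"], p_raw = tab[1, "Pr(>F)"]
    )
  }
  if (!is.null(within_matrix)) {
    k <- ncol(within_matrix)
    if (k < 3) {
      rows[[length(rows) + 1L]] <- stat_row(
        analysis, "Mauchly sphericity", "W", NA,
        method = "not-applicable (2 within levels)"
      )
    } else {
      fit <- lm(within_matrix ~ 1)
      mt <- mauchly.test(fit, X = ~1)
      rows[[length(rows) + 1L]] <- stat_row(
        analysis, "Mauchly sphericity", "W",
        unname(mt$statistic), p_raw = mt$p.value
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
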