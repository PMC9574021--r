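group_factors <- function(group) {
  group <- as.character(group)
  data.frame(
    age = factor(ifelse(grepl("^elderly", group), "elderly", "young"),
      levels = c("young", "elderly")
    ),
    sex = factor(ifelse(grepl("male$", group) & !grepl("female$", group),
      "male", "female"
    ), levels = c("male", "female"))
  )
}

# wide ES table: one row per participant, columns es_<hemi>_<cue>
es_wide <- function(effect_sizes) {
  es <- effect_sizes
  es$key <- paste0(
    "es_", sub("_dlPFC", "", es$roi), "_", es$cue
  )
  ids <- unique(es$participant_id)
  out <- data.frame(
    participant_id = ids,
    group = es$group[match(ids, es$participant_id)],
    stringsAsFactors = FALSE
  )
  for (k in unique(es$key)) {
    sub <- es[es$key == k, ]
    out[[k]] <- sub$effect_size[match(ids, sub$participant_id)]
  }
  cbind(out, group_factors(out$group))
}

#' Placebo/nocebo analysis of a conditioned-cue fNIRS experiment
#'
#' The top-level model fit: runs the full analysis chain — preprocessing
#' (band-pass + systemic-component removal), cue-locked dl-PFC effect sizes,
#' VAS pain indices, and the inferential battery (factorial ANOVAs with
#' Bonferroni post hoc tests, per-group Pearson correlations between the
#' pain-reduction index and the right dl-PFC response to the safe cue with
#' Holm correction, forced-entry and stepwise regressions, Mann-Whitney
#' baseline comparisons, assumption checks) — and returns a classed object
#' with `print`, `summary`, `coef` and `plot` methods.
#'
#' @param x A `cohort_config` (the cohort is simulated and processed
#'   participant-by-participant), a `nirs_cohort`, or a list with elements
#'   `effect_sizes` (participant x ROI x cue table), `vas_table` and
#'   optionally `profiles` (demographics).
#' @param error_model ANOVA error model for the three-way analyses:
#'   `"pooled"` (single error stratum; reproduces the conventional
#'   denominator df of 112 for a 60-participant, 2-condition design) or
#'   `"mixed"` (subject error stratum for the repeated factor).
#' @param holm_variant Holm variant for the correlation family; see
#'   [holm_adjust()].
#' @param montage,chromophores Used only when `x` is a config.
#' @param ... Passed to [participant_effect_sizes()] when recordings are
#'   processed.
#' @return An object of class `placebo_nirs`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 8, seed = 3)
#' fit <- placebo_nirs(cfg, montage = "dlpfc")
#' fit
placebo_nirs <- function(x, error_model = c("pooled", "mixed"),
                         holm_variant = "standard",
                         montage = "full", chromophores = "HbO", ...) {
  error_model <- match.arg(error_model)
  if (inherits(x, "cohort_config") || inherits(x, "nirs_cohort")) {
    x <- cohort_effect_sizes(x,
      montage = montage,
      chromophores = chromophores, ...
    )
  }
  stopifnot(is.list(x), all(c("effect_sizes", "vas_table") %in% names(x)))
  es_long <- x$effect_sizes
  vas <- x$vas_table
  profiles <- x$profiles
  wide <- es_wide(es_long)
  idx <- pain_indices(vas)
  idx <- cbind(idx, group_factors(idx$group))
  dat <- merge(wide, idx[, c(
    "participant_id", "reduction_index",
    "enhancement_index"
  )], by = "participant_id")

  stats <- list()
  results <- list()
  push <- function(res) {
    results[[length(results) + 1L]] <<- res
    res
  }

  if (!is.null(profiles)) {
    pf <- cbind(profiles, group_factors(profiles$group))
    age_em_ef <- mann_whitney_r(
      pf$age[pf$group == "elderly_male"], pf$age[pf$group == "elderly_female"],
      analysis = "age: elderly male vs female"
    )
    age_ym_yf <- mann_whitney_r(
      pf$age[pf$group == "young_male"], pf$age[pf$group == "young_female"],
      analysis = "age: young male vs female"
    )
    mmse <- mann_whitney_r(
      pf$mmse[pf$group == "elderly_male" & !is.na(pf$mmse)],
      pf$mmse[pf$group == "elderly_female" & !is.na(pf$mmse)],
      analysis = "MMSE: elderly male vs female"
    )
    cur_anova <- factorial_anova(
      data.frame(y = pf$max_current, group = pf$group),
      "y", "group",
      analysis = "max current one-way"
    )
    cur_posthoc <- bonferroni_posthoc(pf$max_current, pf$group,
      analysis = "max current post hoc"
    )
    cur_assum <- assumption_checks(pf$max_current, pf$group,
      analysis = "max current assumptions"
    )
    stats$baseline <- push(rbind(
      age_em_ef, age_ym_yf, mmse,
      cur_anova, cur_posthoc, cur_assum
    ))
  }

  # three-way VAS ANOVAs: matched vs mismatched delivery of each shock
  vas2 <- cbind(vas, group_factors(vas$group))
  hs <- vas2[vas2$condition %in% c("HF-HS", "LF-HS"), ]
  hs$condition <- droplevels(factor(hs$condition,
    levels = c("HF-HS", "LF-HS"),
    labels = c("matched", "mismatched")
  ))
  ls <- vas2[vas2$condition %in% c("LF-LS", "HF-LS"), ]
  ls$condition <- droplevels(factor(ls$condition,
    levels = c("LF-LS", "HF-LS"),
    labels = c("matched", "mismatched")
  ))
  stats$vas_hs_anova <- push(factorial_anova(hs, "mean_vas",
    between = c("age", "sex"), within = "condition",
    error_model = error_model, analysis = "VAS HS three-way"
  ))
  stats$vas_ls_anova <- push(factorial_anova(ls, "mean_vas",
    between = c("age", "sex"), within = "condition",
    error_model = error_model, analysis = "VAS LS three-way"
  ))

  stats$reduction_anova <- push(factorial_anova(idx, "reduction_index",
    between = c("age", "sex"), analysis = "reduction index two-way"
  ))
  stats$reduction_posthoc <- push(bonferroni_posthoc(
    idx$reduction_index, idx$group,
    analysis = "reduction index post hoc"
  ))
  stats$enhancement_anova <- push(factorial_anova(idx, "enhancement_index",
    between = c("age", "sex"), analysis = "enhancement index two-way"
  ))
  stats$index_assumptions <- push(assumption_checks(
    idx$reduction_index, idx$group,
    analysis = "reduction index assumptions"
  ))

  # three-way ES ANOVAs per hemisphere (age x sex x cue)
  es2 <- cbind(es_long, group_factors(es_long$group))
  for (roi in unique(as.character(es_long$roi))) {
    sub <- es2[es2$roi == roi, ]
    nm <- paste0("es_", sub("_dlPFC", "", roi), "_anova")
    stats[[nm]] <- push(factorial_anova(sub, "effect_size",
      between = c("age", "sex"), within = "cue",
      error_model = error_model,
      analysis = paste(sub("_dlPFC", " dl-PFC", roi), "ES three-way")
    ))
  }
  if ("es_right_LF" %in% names(dat) && "es_right_HF" %in% names(dat)) {
    both <- (dat$es_right_LF + dat$es_right_HF) / 2
    stats$es_right_posthoc <- push(bonferroni_posthoc(both, dat$group,
      analysis = "right dl-PFC ES post hoc"
    ))
  }

  # per-group coupling: reduction index vs right dl-PFC response to safe cue
  if ("es_right_LF" %in% names(dat)) {
    stats$reduction_cor_right <- push(pearson_with_holm(
      dat$es_right_LF, dat$reduction_index, dat$group,
      variant = holm_variant,
      analysis = "reduction ~ right dl-PFC LF ES"
    ))
  }
  if ("es_left_LF" %in% names(dat)) {
    stats$reduction_cor_left <- push(pearson_with_holm(
      dat$es_left_LF, dat$reduction_index, dat$group,
      variant = holm_variant,
      analysis = "reduction ~ left dl-PFC LF ES"
    ))
  }
  if ("es_right_HF" %in% names(dat)) {
    stats$enhancement_cor_right <- push(pearson_with_holm(
      dat$es_right_HF, dat$enhancement_index, dat$group,
      variant = holm_variant,
      analysis = "enhancement ~ right dl-PFC HF ES"
    ))
  }

  pred_red <- intersect(
    c("sex", "age", "es_right_LF", "es_left_LF"),
    names(dat)
  )
  if (all(c("es_right_LF") %in% pred_red)) {
    stats$reduction_regression <- push(regression_forced(
      dat$reduction_index, dat[, pred_red],
      analysis = "reduction forced-entry regression"
    ))
    stats$reduction_stepwise_01 <- push(regression_stepwise(
      dat$reduction_index, dat[, pred_red],
      alpha_enter = 0.01,
      analysis = "reduction stepwise (p < 0.01)"
    ))
    stats$reduction_stepwise_05 <- push(regression_stepwise(
      dat$reduction_index, dat[, pred_red],
      alpha_enter = 0.05,
      analysis = "reduction stepwise (p < 0.05)"
    ))
  }
  pred_enh <- intersect(c("sex", "age", "es_right_HF", "es_left_HF"), names(dat))
  if ("es_right_HF" %in% pred_enh) {
    stats$enhancement_regression <- push(regression_forced(
      dat$enhancement_index, dat[, pred_enh],
      analysis = "enhancement forced-entry regression"
    ))
  }

  structure(
    list(
      data = dat, effect_sizes = es_long, vas_table = vas,
      pain_indices = idx, profiles = profiles,
      stats = stats, results = do.call(rbind, results),
      options = list(error_model = error_model, holm_variant = holm_variant)
    ),
    class = "placebo_nirs"
  )
}

#' @export
print.placebo_nirs <- function(x, ...) {
  cat(sprintf(
    "<placebo_nirs> %d participants, %d inferential results (error model: %s)\n",
    nrow(x$data), nrow(x$results), x$options$error_model
  ))
  means <- tapply(x$pain_indices$reduction_index, x$pain_indices$group, mean)
  cat("mean pain-reduction index by group:\n")
  print(round(means, 2))
  if (!is.null(x$stats$reduction_cor_right)) {
    cr <- x$stats$reduction_cor_right
    cat("reduction ~ right dl-PFC LF ES (Pearson r, Holm-adjusted p):\n")
    print(data.frame(
      group = cr$term, r = round(cr$value, 3),
      p_raw = signif(cr$p_raw, 3), p_holm = signif(cr$p_adjusted, 3)
    ), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.placebo_nirs <- function(object, ...) {
  structure(list(fit = object), class = "summary.placebo_nirs")
}

#' @export
print.summary.placebo_nirs <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nAll inferential results:\n")
  res <- fit$results
  res$value <- signif(res$value, 4)
  res$p_raw <- signif(res$p_raw, 3)
  res$p_adjusted <- signif(res$p_adjusted, 3)
  print(res, row.names = FALSE)
  invisible(x)
}

#' @export
coef.placebo_nirs <- function(object, ...) {
  reg <- object$stats$reduction_regression
  if (is.null(reg)) {
    return(numeric(0))
  }
  b <- reg[reg$statistic == "beta", ]
  setNames(b$value, b$term)
}

#' @export
plot.placebo_nirs <- function(x, ...) {
  dat <- x$data
  if (!"es_right_LF" %in% names(dat)) {
    stop_invalid("fit carries no right dl-PFC LF effect sizes to plot")
  }
  groups <- levels(droplevels(factor(dat$group)))
  old <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (g in groups) {
    sub <- dat[dat$group == g, ]
    plot(sub$es_right_LF, sub$reduction_index,
      xlab = "right dl-PFC ES (LF cue)", ylab = "pain reduction index",
      main = g, pch = 19, ...
    )
    if (nrow(sub) > 2 && sd(sub$es_right_LF) > 0) {
      abline(lm(reduction_index ~ es_right_LF, data = sub), col = 2)
    }
  }
  invisible(x)
}

#' Write the tidy results table of a fit
#'
#' @param fit A `placebo_nirs` object.
#' @param path Output path for the tab-separated results table.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "placebo_nirs"))
  write.table(fit$results, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
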