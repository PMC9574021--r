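#' End-to-end replication check of the group-level pattern
#'
#' Simulates one cohort at the default group parameters, runs the full
#' pipeline, and checks whether it reproduces the study's qualitative
#' behavioral/hemodynamic pattern: the elderly-female group has the largest
#' mean pain-reduction index, both male groups exceed the young-female group,
#' and the young-female correlation between the reduction index and the right
#' dl-PFC response to the safe (LF) cue is non-significant (p >= 0.05).
#'
#' @param seed Master seed for the simulated cohort.
#' @param n_per_group Participants per group (default 15, the study size).
#' @param montage Geometry montage; the right-dl-PFC montage suffices since
#'   only right-hemisphere effect sizes enter the pattern.
#' @param alpha Significance level for the correlation check (default 0.05).
#' @return A list: `ordering_ok`, `yf_nonsignificant`, `recovered` (both),
#'   `means` (group mean reduction indices), `cors` (per-group r),
#'   `p_young_female`.
#' @export
#' @examples
#' \donttest{
#' replicate_group_pattern(seed = 1)$recovered
#' }
replicate_group_pattern <- function(seed, n_per_group = 15,
                                    montage = "right_dlpfc", alpha = 0.05) {
  cfg <- cohort_config(n_per_group = n_per_group, seed = seed)
  res <- cohort_effect_sizes(cfg, montage = montage, chromophores = "HbO")
  es <- res$effect_sizes
  sub <- es[es$roi == "right_dlPFC" & es$cue == "LF", ]
  idx <- pain_indices(res$vas_table)
  m <- merge(sub[, c("participant_id", "group", "effect_size")],
    idx[, c("participant_id", "reduction_index")],
    by = "participant_id"
  )
  means <- tapply(m$reduction_index, m$group, mean)
  cors <- vapply(split(m, m$group), function(d) {
    cor(d$effect_size, d$reduction_index)
  }, numeric(1))
  yf <- m[m$group == "young_female", ]
  p_yf <- cor.test(yf$effect_size, yf$reduction_index)$p.value
  ordering_ok <- means[["elderly_female"]] > means[["elderly_male"]] &&
    means[["elderly_female"]] > means[["young_male"]] &&
    means[["elderly_male"]] > means[["young_female"]] &&
    means[["young_male"]] > means[["young_female"]]
  list(
    ordering_ok = ordering_ok,
    yf_nonsignificant = p_yf >= alpha,
    recovered = ordering_ok && p_yf >= alpha,
    means = means, cors = cors, p_young_female = p_yf
  )
}
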