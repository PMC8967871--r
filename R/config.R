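#' Study design configuration
#'
#' Describes the structural side of a simulated session: cohort sizes,
#' trial counts, saliva sampling grid and the phase schedule of the
#' recording. Defaults reproduce the reference design: 64 experimental
#' trials per session (split equally between rule- and plan-based
#' approaches), cortisol sampled at -30, 0, +10, +20 and +40 min
#' relative to stressor onset, and a 20-min baseline followed by three
#' 30-min sessions (pre-manipulation, TSST, post-manipulation), each
#' holding three contiguous 10-min heart-rate/HRV intervals.
#'
#' @param n_stress,n_control participants per group (each >= 2).
#' @param trials_per_session experimental trials per session; must be
#'   even so the two approaches are balanced.
#' @param training_trials training trials preceding session 1 (kept for
#'   schedule realism; no trial records are emitted for them).
#' @param technical_failure_rate probability a trial is lost to a
#'   technical recording problem.
#' @param cortisol_times_min saliva sampling times, minutes relative to
#'   stressor onset; strictly increasing.
#' @param phase_minutes named durations (minutes) of the recording
#'   phases `baseline`, `pre`, `tsst`, `post`.
#' @param rng_seed integer seed; identical configs and seed give
#'   bit-identical cohorts.
#' @return A list of class `rpmc_design`.
#' @seealso [effect_config()], [generate_cohort()]
#' @export
design_config <- function(n_stress = 19L,
                          n_control = 17L,
                          trials_per_session = 64L,
                          training_trials = 8L,
                          technical_failure_rate = 0.0189,
                          cortisol_times_min = c(-30, 0, 10, 20, 40),
                          phase_minutes = c(baseline = 20, pre = 30,
                                            tsst = 30, post = 30),
                          rng_seed = 1L) {
  if (!is.numeric(n_stress) || length(n_stress) != 1 || n_stress < 2)
    stop_config("n_stress", "must be a single count >= 2")
  if (!is.numeric(n_control) || length(n_control) != 1 || n_control < 2)
    stop_config("n_control", "must be a single count >= 2")
  if (!is.numeric(trials_per_session) || trials_per_session < 2 ||
      trials_per_session %% 2 != 0)
    stop_config("trials_per_session",
                "must be an even count (balanced across approaches)")
  if (!is.numeric(training_trials) || training_trials < 0)
    stop_config("training_trials", "must be a non-negative count")
  if (!is.numeric(technical_failure_rate) ||
      technical_failure_rate < 0 || technical_failure_rate > 1)
    stop_config("technical_failure_rate", "must be a probability in [0, 1]")
  if (length(cortisol_times_min) < 2 ||
      any(diff(cortisol_times_min) <= 0))
    stop_config("cortisol_times_min", "must be strictly increasing")
  needed <- c("baseline", "pre", "tsst", "post")
  if (!all(needed %in% names(phase_minutes)))
    stop_config("phase_minutes",
                paste("must name phases:", paste(needed, collapse = ", ")))
  if (any(phase_minutes[needed] <= 0))
    stop_config("phase_minutes", "phase durations must be positive")
  if (!is.numeric(rng_seed) || length(rng_seed) != 1 || is.na(rng_seed))
    stop_config("rng_seed", "must be a single integer")

  structure(list(
    n_stress = as.integer(n_stress),
    n_control = as.integer(n_control),
    trials_per_session = as.integer(trials_per_session),
    training_trials = as.integer(training_trials),
    technical_failure_rate = technical_failure_rate,
    cortisol_times_min = as.numeric(cortisol_times_min),
    phase_minutes = phase_minutes[needed],
    rng_seed = as.integer(rng_seed)
  ), class = "rpmc_design")
}

#' Planted effect structure for the synthetic cohort
#'
#' Ground-truth generative parameters. Response and movement times are
#' log-normal with effects acting on the cell mean (ms scale); the
#' RR-interval generator plants per-interval heart-rate and RMSSD
#' targets; cortisol follows a flat afternoon baseline plus, in the
#' stress group, a log-normal pulse peaking ~20 min after stressor
#' onset. The group-by-RMSSD moderation is planted by letting each
#' participant's post-minus-pre plan-based improvement depend linearly
#' on that participant's planted AUC_I of ln RMSSD, with group-specific
#' slope (`rmssd_slope_control` for controls, plus
#' `rmssd_moderation_slope` in the stress group).
#'
#' Default magnitudes emulate the reference study's reported pattern: a
#' rule-based response-time advantage, a general session improvement
#' with a larger plan-based gain, TSST-phase heart-rate elevation and
#' RMSSD withdrawal in the stress group, and a cortisol rise peaking
#' 10-20 min post onset.
#'
#' @param rt_grand_mean grand mean response time, ms.
#' @param rule_advantage_rt how much faster rule-based trials are, ms.
#' @param session_gain_rt general pre-to-post RT improvement, ms.
#' @param plan_extra_gain_rt additional plan-based improvement
#'   (session-by-approach interaction), ms.
#' @param error_rate_rule,error_rate_plan per-approach error
#'   probabilities, each in \[0, 0.5\].
#' @param mt_grand_mean,mt_session_gain movement-time mean and
#'   session improvement, ms.
#' @param rr_mean mean RR interval, ms.
#' @param hr_tsst_delta_stress TSST-phase heart-rate elevation in the
#'   stress group, bpm.
#' @param rmssd_baseline baseline RMSSD, ms.
#' @param rmssd_tsst_delta_stress TSST-phase RMSSD change in the stress
#'   group, ms (negative = vagal withdrawal).
#' @param cortisol_baseline,cortisol_peak_delta_stress baseline level
#'   and stress-group peak increase, nmol/L.
#' @param rmssd_slope_control,rmssd_moderation_slope moderation slopes,
#'   BI-units per AUC_I-unit (ln(ms) x min); the moderation slope is the
#'   stress-minus-control slope difference targeted by the regression.
#' @param bi_ms_per_unit ms of response time treated as one BI unit when
#'   planting the moderation (approximate pooled SD of cell-mean RTs).
#' @param noise named list of dispersion parameters; set all to zero for
#'   a fully deterministic cohort. `artifact_fraction` is the fraction
#'   of RR beats corrupted by missed/spurious-beat artifacts (must stay
#'   below 0.10).
#' @return A list of class `rpmc_effects`.
#' @export
effect_config <- function(rt_grand_mean = 1000,
                          rule_advantage_rt = 120,
                          session_gain_rt = 80,
                          plan_extra_gain_rt = 60,
                          error_rate_rule = 0.03,
                          error_rate_plan = 0.07,
                          mt_grand_mean = 1200,
                          mt_session_gain = 150,
                          rr_mean = 800,
                          hr_tsst_delta_stress = 15,
                          rmssd_baseline = 45,
                          rmssd_tsst_delta_stress = -15,
                          cortisol_baseline = 10,
                          cortisol_peak_delta_stress = 8,
                          rmssd_slope_control = -0.125,
                          rmssd_moderation_slope = 0.125,
                          bi_ms_per_unit = 120,
                          noise = list()) {
  noise_defaults <- list(
    rt_log_sd = 0.25,          # within-trial log-RT dispersion
    rt_between_log_sd = 0.10,  # participant speed factor, log scale
    mt_log_sd = 0.20,
    mt_between_log_sd = 0.08,
    rr_between_sd = 60,        # between-participant RR mean, ms
    hr_react_sd = 7,           # TSST heart-rate reactivity, bpm
    rmssd_between_sd = 12,     # between-participant RMSSD, ms
    rmssd_react_sd = 12,       # TSST RMSSD reactivity, ms
    cortisol_between_sd = 2,
    cortisol_react_sd = 5,
    cortisol_noise_sd = 1,
    artifact_fraction = 0.015
  )
  unknown <- setdiff(names(noise), names(noise_defaults))
  if (length(unknown))
    stop_config("noise", paste("unknown noise scale(s):",
                               paste(unknown, collapse = ", ")))
  noise <- modifyList(noise_defaults, noise)

  for (f in c("rt_grand_mean", "mt_grand_mean", "rr_mean",
              "rmssd_baseline", "cortisol_baseline", "bi_ms_per_unit")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stop_config(f, "must be a single positive number")
  }
  for (f in c("error_rate_rule", "error_rate_plan")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 0.5)
      stop_config(f, "must be a probability in [0, 0.5]")
  }
  bad <- names(noise)[vapply(noise, function(v)
    !is.numeric(v) || length(v) != 1 || v < 0, logical(1))]
  if (length(bad))
    stop_config("noise", paste("non-negative scalars required:",
                               paste(bad, collapse = ", ")))
  if (noise$artifact_fraction >= 0.10)
    stop_config("noise$artifact_fraction",
                "artifact fractions of 10% or more are not supported")

  structure(list(
    rt_grand_mean = rt_grand_mean,
    rule_advantage_rt = rule_advantage_rt,
    session_gain_rt = session_gain_rt,
    plan_extra_gain_rt = plan_extra_gain_rt,
    error_rate_rule = error_rate_rule,
    error_rate_plan = error_rate_plan,
    mt_grand_mean = mt_grand_mean,
    mt_session_gain = mt_session_gain,
    rr_mean = rr_mean,
    hr_tsst_delta_stress = hr_tsst_delta_stress,
    rmssd_baseline = rmssd_baseline,
    rmssd_tsst_delta_stress = rmssd_tsst_delta_stress,
    cortisol_baseline = cortisol_baseline,
    cortisol_peak_delta_stress = cortisol_peak_delta_stress,
    rmssd_slope_control = rmssd_slope_control,
    rmssd_moderation_slope = rmssd_moderation_slope,
    bi_ms_per_unit = bi_ms_per_unit,
    noise = noise
  ), class = "rpmc_effects")
}

#' Effect configuration with every planted effect set to zero
#'
#' Convenience constructor for null-effect and deterministic scenarios:
#' all group deltas, session/approach effects and moderation slopes are
#' 0 and (optionally) all noise scales are 0. In the stochastic variant
#' the per-approach error rates stay at an equal 0.05 — proportion
#' correct must vary for BI standardization to be defined — while the
#' fully deterministic variant zeroes them too.
#'
#' @param keep_noise if `TRUE`, retain the default noise scales (a
#'   null-effect but stochastic cohort, used for type-I-error checks).
#' @return An `rpmc_effects` object.
#' @export
null_effects <- function(keep_noise = TRUE) {
  noise <- if (keep_noise) list(artifact_fraction = 0) else list(
    rt_log_sd = 0, rt_between_log_sd = 0, mt_log_sd = 0,
    mt_between_log_sd = 0, rr_between_sd = 0, hr_react_sd = 0,
    rmssd_between_sd = 0, rmssd_react_sd = 0, cortisol_between_sd = 0,
    cortisol_react_sd = 0, cortisol_noise_sd = 0, artifact_fraction = 0)
  err <- if (keep_noise) 0.05 else 0
  effect_config(
    rule_advantage_rt = 0, session_gain_rt = 0, plan_extra_gain_rt = 0,
    error_rate_rule = err, error_rate_plan = err, mt_session_gain = 0,
    hr_tsst_delta_stress = 0, rmssd_tsst_delta_stress = 0,
    cortisol_peak_delta_stress = 0,
    rmssd_slope_control = 0, rmssd_moderation_slope = 0,
    noise = noise)
}

# Phase boundary helpers ------------------------------------------------

# Absolute start times (minutes from recording start) of the phases and
# the 9 HR/HRV intervals; stressor onset = start of the TSST phase.
phase_layout <- function(design) {
  pm <- design$phase_minutes
  starts <- cumsum(c(0, pm))[1:4]
  names(starts) <- names(pm)
  onset <- starts[["tsst"]]
  interval_starts <- c(
    starts[["pre"]] + (0:2) * pm[["pre"]] / 3,
    starts[["tsst"]] + (0:2) * pm[["tsst"]] / 3,
    starts[["post"]] + (0:2) * pm[["post"]] / 3
  )
  list(phase_starts = starts,
       total_min = sum(pm),
       onset_min = onset,
       interval_starts_min = interval_starts,
       interval_len_min = pm[["pre"]] / 3)
}
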