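# Synthetic cohort generator. Everything stochastic is driven by the
# design's rng_seed through withr::with_seed, so identical configs give
# bit-identical cohorts.

# Planted AUC_I of a marker trajectory given at interval midpoints:
# trapezoid minus first-value rectangle (Pruessner-style increase area).
planted_auc_i <- function(times, values) {
  pracma::trapz(times, values) - values[1] * (times[length(times)] - times[1])
}

# Draw one participant's latent profile: subject random effects, planted
# per-interval HR / RMSSD targets, cortisol parameters, covariates, and
# the moderation shift applied to post-session plan-based trials.
draw_profile <- function(id, group, design, effects) {
  nz <- effects$noise
  stress <- identical(group, "stress")
  lay <- phase_layout(design)

  rt_subj <- rnorm(1, 0, nz$rt_between_log_sd)
  mt_subj <- rnorm(1, 0, nz$mt_between_log_sd)

  rr_base <- max(450, effects$rr_mean + rnorm(1, 0, nz$rr_between_sd))
  hr_delta <- (if (stress) effects$hr_tsst_delta_stress else 0) +
    rnorm(1, 0, nz$hr_react_sd)
  rmssd_base <- max(8, effects$rmssd_baseline + rnorm(1, 0, nz$rmssd_between_sd))
  rmssd_delta <- (if (stress) effects$rmssd_tsst_delta_stress else 0) +
    rnorm(1, 0, nz$rmssd_react_sd)
  rmssd_delta <- max(rmssd_delta, 4 - rmssd_base)  # keep TSST RMSSD >= 4 ms

  cort_base <- max(1, effects$cortisol_baseline +
                     rnorm(1, 0, nz$cortisol_between_sd))
  cort_delta <- if (stress)
    max(0, effects$cortisol_peak_delta_stress + rnorm(1, 0, nz$cortisol_react_sd))
  else 0

  age <- round(min(32, max(18, rnorm(1, 22.95, 3.34))))
  bmi <- round(min(29, max(17.5, rnorm(1, 22.87, 2.58))), 1)

  tsst_iv <- 4:6  # intervals t4..t6 lie inside the TSST session
  hr_targets <- rep(60000 / rr_base, 9)
  hr_targets[tsst_iv] <- hr_targets[tsst_iv] + hr_delta
  rmssd_targets <- rep(rmssd_base, 9)
  rmssd_targets[tsst_iv] <- rmssd_targets[tsst_iv] + rmssd_delta

  mid_min <- lay$interval_starts_min + lay$interval_len_min / 2 - lay$onset_min
  w <- 3:7  # HR / RMSSD analysis window t3-t7
  a_lnrmssd <- planted_auc_i(mid_min[w], log(rmssd_targets[w]))
  a_lnhr <- planted_auc_i(mid_min[w], log(hr_targets[w]))

  slope <- effects$rmssd_slope_control +
    (if (stress) effects$rmssd_moderation_slope else 0)
  plan_shift_ms <- effects$bi_ms_per_unit * slope * a_lnrmssd

  pre_rule <- effects$rt_grand_mean - effects$rule_advantage_rt / 2
  pre_plan <- effects$rt_grand_mean + effects$rule_advantage_rt / 2
  rt_means <- c(
    pre.rule = pre_rule,
    pre.plan = pre_plan,
    post.rule = pre_rule - effects$session_gain_rt,
    post.plan = max(150, pre_plan - effects$session_gain_rt -
                      effects$plan_extra_gain_rt - plan_shift_ms)
  )
  mt_means <- c(pre = effects$mt_grand_mean,
                post = max(150, effects$mt_grand_mean - effects$mt_session_gain))

  list(id = id, group = group, age = age, bmi = bmi,
       rt_subj = rt_subj, mt_subj = mt_subj,
       rr_base = rr_base, hr_targets = hr_targets,
       rmssd_targets = rmssd_targets,
       cort_base = cort_base, cort_delta = cort_delta,
       a_lnrmssd = a_lnrmssd, a_lnhr = a_lnhr,
       plan_shift_ms = plan_shift_ms,
       rt_means = rt_means, mt_means = mt_means)
}

#' Generate movement-selection trial records for one participant
#'
#' Response times are log-normal with the cell mean (participant's
#' planted mean times a subject speed factor) as the exact expectation,
#' so zero noise reproduces the configured cell means identically.
#' Trial correctness is Bernoulli with per-approach error rates and the
#' two approaches are balanced (half the trials each) within a session.
#'
#' @param profile participant profile as built inside [generate_cohort()].
#' @param design an [design_config()] object.
#' @param effects an [effect_config()] object.
#' @return Data frame of trial records for both sessions with columns
#'   `participant_id, group, session, approach, trial_index, rt_ms,
#'   mt_ms, correct, technical_error, outlier`.
#' @export
generate_trials <- function(profile, design, effects) {
  tps <- design$trials_per_session
  nz <- effects$noise
  out <- vector("list", 2)
  for (k in 1:2) {
    session <- c("pre", "post")[k]
    approach <- sample(rep(c("rule", "plan"), each = tps / 2))
    cell <- paste(session, approach, sep = ".")
    m_rt <- profile$rt_means[cell] * exp(profile$rt_subj)
    rt <- rlnorm(tps, meanlog = log(m_rt) - nz$rt_log_sd^2 / 2,
                 sdlog = nz$rt_log_sd)
    m_mt <- profile$mt_means[session] * exp(profile$mt_subj)
    mt <- rlnorm(tps, meanlog = log(m_mt) - nz$mt_log_sd^2 / 2,
                 sdlog = nz$mt_log_sd)
    err <- ifelse(approach == "rule", effects$error_rate_rule,
                  effects$error_rate_plan)
    correct <- runif(tps) >= err
    technical <- runif(tps) < design$technical_failure_rate
    out[[k]] <- data.frame(
      participant_id = profile$id, group = profile$group,
      session = session, approach = approach, trial_index = seq_len(tps),
      rt_ms = rt, mt_ms = mt, correct = correct,
      technical_error = technical, outlier = FALSE,
      stringsAsFactors = FALSE)
  }
  rbind(out[[1]], out[[2]])
}

#' Generate a beat-to-beat RR-interval series for one participant
#'
#' Beats are generated phase by phase: within each 10-min interval the
#' RR mean is set by the planted heart-rate target and successive-beat
#' variability by the planted RMSSD target (independent Gaussian
#' deviations; for i.i.d. deviations with SD s the expected RMSSD is
#' s*sqrt(2), so s = target/sqrt(2)). A configurable fraction of beats
#' is corrupted to emulate missed beats (doubled RR) or spurious beats
#' (one interval split into two halves).
#'
#' @inheritParams generate_trials
#' @param artifact_fraction fraction of beats corrupted; must be < 0.10.
#' @return Data frame with columns `participant_id, beat_time_s, rr_ms,
#'   phase, artifact` (ground-truth corruption mask).
#' @export
generate_rr_series <- function(profile, design, effects,
                               artifact_fraction = effects$noise$artifact_fraction) {
  if (!is.numeric(artifact_fraction) || artifact_fraction < 0)
    stop_config("artifact_fraction", "must be a non-negative fraction")
  if (artifact_fraction >= 0.10)
    stop_config("artifact_fraction",
                "artifact fractions of 10% or more are not supported")
  lay <- phase_layout(design)
  # one generation block per constant-target stretch: baseline + 9 intervals
  dur_min <- c(design$phase_minutes[["baseline"]], rep(lay$interval_len_min, 9))
  hr <- c(60000 / profile$rr_base, profile$hr_targets)
  rmssd <- c(profile$rmssd_targets[1], profile$rmssd_targets)

  rr_all <- vector("list", length(dur_min))
  for (b in seq_along(dur_min)) {
    dur_ms <- dur_min[b] * 60000
    target_rr <- 60000 / hr[b]
    s <- rmssd[b] / sqrt(2)
    n_guess <- ceiling(dur_ms / max(300, target_rr - 6 * s)) + 5
    rr <- pmax(300, target_rr + rnorm(n_guess, 0, s))
    keep <- cumsum(rr) <= dur_ms
    rr_all[[b]] <- rr[keep]
  }
  rr <- unlist(rr_all, use.names = FALSE)
  artifact <- rep(FALSE, length(rr))

  n_art <- round(artifact_fraction * length(rr))
  if (n_art > 0) {
    idx <- sort(sample(length(rr), n_art))
    split_beat <- runif(n_art) < 0.5
    for (j in rev(seq_len(n_art))) {
      i <- idx[j]
      if (split_beat[j]) {  # spurious beat: one interval becomes two halves
        rr <- append(rr[-i], rep(rr[i] / 2, 2), after = i - 1)
        artifact <- append(artifact[-i], c(TRUE, TRUE), after = i - 1)
      } else {              # missed beat: doubled interval
        rr[i] <- 2 * rr[i]
        artifact[i] <- TRUE
      }
    }
  }

  beat_time_s <- cumsum(rr) / 1000
  bounds_s <- c(lay$phase_starts[-1], lay$total_min) * 60
  phase <- c("baseline", "pre", "TSST", "post")[
    findInterval(beat_time_s, bounds_s) + 1]
  phase[phase == "5" | is.na(phase)] <- "post"

  data.frame(participant_id = profile$id, beat_time_s = beat_time_s,
             rr_ms = rr, phase = phase, artifact = artifact,
             stringsAsFactors = FALSE)
}

#' Generate a salivary cortisol series for one participant
#'
#' Controls follow a flat afternoon baseline plus measurement noise;
#' stress participants additionally show a log-normal secretory pulse
#' starting at stressor onset and peaking 20 min later.
#'
#' @inheritParams generate_trials
#' @return Data frame with columns `participant_id, label, time_min,
#'   cortisol_nmol_l` (times in minutes relative to stressor onset).
#' @export
generate_cortisol <- function(profile, design, effects) {
  t <- design$cortisol_times_min
  shape <- cortisol_pulse_shape(t)
  v <- profile$cort_base + profile$cort_delta * shape +
    rnorm(length(t), 0, effects$noise$cortisol_noise_sd)
  data.frame(participant_id = profile$id,
             label = paste0("t", seq_along(t)),
             time_min = t,
             cortisol_nmol_l = pmax(0.5, v),
             stringsAsFactors = FALSE)
}

# Unit-peak log-normal pulse, maximum at +20 min after onset, zero before.
cortisol_pulse_shape <- function(t_min, peak_min = 20, width = 0.5) {
  shape <- numeric(length(t_min))
  pos <- t_min > 0
  shape[pos] <- exp(-(log(t_min[pos] / peak_min))^2 / (2 * width^2))
  shape
}

#' Generate a complete synthetic cohort
#'
#' Builds one trial-record set, one RR beat series and one cortisol
#' series per participant, together with a ground-truth record of every
#' planted parameter (enabling recovery tests downstream). All
#' randomness derives from `design$rng_seed`; the same configs produce
#' bit-identical cohorts.
#'
#' @param design an [design_config()] object.
#' @param effects an [effect_config()] object.
#' @param components which data channels to generate; dropping `"beats"`
#'   makes large simulation sweeps over purely behavioural cohorts cheap.
#' @return An object of class `rpmc_cohort`: a list with data frames
#'   `trials`, `beats`, `cortisol`, `participants` and a `ground_truth`
#'   list echoing the configuration plus per-participant planted values.
#' @examples
#' coh <- generate_cohort(design_config(n_stress = 2, n_control = 2,
#'                                      trials_per_session = 8))
#' table(coh$trials$session, coh$trials$approach)
#' @export
generate_cohort <- function(design = design_config(),
                            effects = effect_config(),
                            components = c("trials", "beats", "cortisol")) {
  stopifnot(inherits(design, "rpmc_design"), inherits(effects, "rpmc_effects"))
  components <- match.arg(components, several.ok = TRUE)
  groups <- c(rep("stress", design$n_stress), rep("control", design$n_control))
  ids <- sprintf("P%02d", seq_along(groups))

  withr::with_seed(design$rng_seed, {
    profiles <- mapply(draw_profile, ids, groups,
                       MoreArgs = list(design = design, effects = effects),
                       SIMPLIFY = FALSE)
    trials <- if ("trials" %in% components)
      do.call(rbind, lapply(profiles, generate_trials, design, effects))
    beats <- if ("beats" %in% components)
      do.call(rbind, lapply(profiles, generate_rr_series, design, effects))
    cortisol <- if ("cortisol" %in% components)
      do.call(rbind, lapply(profiles, generate_cortisol, design, effects))
  })

  participants <- data.frame(
    participant_id = ids, group = groups,
    age = vapply(profiles, `[[`, numeric(1), "age"),
    bmi = vapply(profiles, `[[`, numeric(1), "bmi"),
    stringsAsFactors = FALSE)

  planted <- data.frame(
    participant_id = ids, group = groups,
    a_lnrmssd = vapply(profiles, `[[`, numeric(1), "a_lnrmssd"),
    a_lnhr = vapply(profiles, `[[`, numeric(1), "a_lnhr"),
    plan_shift_ms = vapply(profiles, `[[`, numeric(1), "plan_shift_ms"),
    stringsAsFactors = FALSE)
  rownames(participants) <- rownames(planted) <- NULL

  structure(list(
    trials = if ("trials" %in% components) `rownames<-`(trials, NULL),
    beats = if ("beats" %in% components) `rownames<-`(beats, NULL),
    cortisol = if ("cortisol" %in% components) `rownames<-`(cortisol, NULL),
    participants = participants,
    ground_truth = list(design = unclass(design), effects = unclass(effects),
                        planted = planted)
  ), class = "rpmc_cohort")
}

#' Participant-level marker/change-score simulator
#'
#' Reduced-form companion to [generate_cohort()] for large simulation
#' sweeps (moderation recovery, type-I calibration of the regression):
#' it draws the same latent participant profiles, then emits
#' participant-level AUC_I markers and BI change scores directly instead
#' of resampling every beat and trial. Cortisol AUC_I is computed from
#' noisy simulated samples; HR and RMSSD AUC_I are the planted values
#' plus the (small) estimation noise of the windowed extractor. Change
#' scores follow the planted moderation structure: the plan-based change
#' depends linearly on the participant's AUC_I of ln RMSSD with
#' group-specific slope.
#'
#' @param n_stress,n_control group sizes.
#' @param effects an [effect_config()] object.
#' @param trials_per_session used to size the trial-averaging noise of
#'   the change scores.
#' @param seed integer seed.
#' @return Data frame with one row per participant: `participant_id,
#'   group, group01, auc_lncort, auc_lnhr, auc_lnrmssd, bmi, age,
#'   change_plan, change_rule`.
#' @export
simulate_marker_summaries <- function(n_stress, n_control,
                                      effects = effect_config(),
                                      trials_per_session = 64,
                                      seed = 1L) {
  design <- design_config(n_stress = max(2, n_stress),
                          n_control = max(2, n_control),
                          trials_per_session = trials_per_session,
                          rng_seed = as.integer(seed))
  nz <- effects$noise
  groups <- c(rep("stress", n_stress), rep("control", n_control))
  ids <- sprintf("P%02d", seq_along(groups))
  n_rt <- trials_per_session / 2
  sd_cell <- effects$rt_grand_mean * nz$rt_log_sd / sqrt(n_rt)
  # change-score noise: two cell means plus an accuracy (z-PC) component
  change_sd <- sqrt(2 * (sd_cell / effects$bi_ms_per_unit)^2 + 0.3^2)

  withr::with_seed(design$rng_seed, {
    rows <- lapply(seq_along(ids), function(i) {
      p <- draw_profile(ids[i], groups[i], design, effects)
      stress <- groups[i] == "stress"
      cort <- generate_cortisol(p, design, effects)
      a_cort <- planted_auc_i(cort$time_min[2:5], log(cort$cortisol_nmol_l[2:5]))
      a_rmssd <- p$a_lnrmssd + rnorm(1, 0, 0.5)   # windowed-estimator noise
      a_hr <- p$a_lnhr + rnorm(1, 0, 0.05)
      slope <- effects$rmssd_slope_control +
        (if (stress) effects$rmssd_moderation_slope else 0)
      change_plan <- (effects$session_gain_rt + effects$plan_extra_gain_rt) /
        effects$bi_ms_per_unit + slope * a_rmssd + rnorm(1, 0, change_sd)
      change_rule <- effects$session_gain_rt / effects$bi_ms_per_unit +
        rnorm(1, 0, change_sd)
      data.frame(participant_id = ids[i], group = groups[i],
                 group01 = as.integer(stress),
                 auc_lncort = a_cort, auc_lnhr = a_hr, auc_lnrmssd = a_rmssd,
                 bmi = p$bmi, age = p$age,
                 change_plan = change_plan, change_rule = change_rule,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
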