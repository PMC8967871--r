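# Synthetic cohort generator: structure, determinism, planted-parameter
# recovery.

test_that("config validation names the offending field", {
  expect_error(design_config(n_stress = 1), "n_stress",
               class = "rpmc_config_error")
  expect_error(design_config(trials_per_session = 63), "trials_per_session",
               class = "rpmc_config_error")
  expect_error(design_config(cortisol_times_min = c(0, 0, 10)),
               "cortisol_times_min", class = "rpmc_config_error")
  expect_error(effect_config(error_rate_plan = 0.7), "error_rate_plan",
               class = "rpmc_config_error")
  expect_error(effect_config(noise = list(artifact_fraction = 0.2)),
               "artifact_fraction", class = "rpmc_config_error")
})

test_that("cohorts have the configured shape and are seed-deterministic", {
  d <- quick_design(seed = 11)
  e <- effect_config()
  coh <- generate_cohort(d, e)

  # 16 experimental trials per session, balanced across approaches
  tab <- table(coh$trials$participant_id, coh$trials$session,
               coh$trials$approach)
  expect_true(all(tab == d$trials_per_session / 2))
  expect_equal(nrow(coh$participants), 8)
  expect_setequal(unique(coh$trials$group), c("stress", "control"))

  # beat times strictly increasing and consistent with cumulative RR
  for (pid in c("P01", "P05")) {
    b <- coh$beats[coh$beats$participant_id == pid, ]
    expect_true(all(diff(b$beat_time_s) > 0))
    expect_equal(diff(b$beat_time_s) * 1000, b$rr_ms[-1], tolerance = 1e-9)
    expect_true(all(b$rr_ms > 0))
  }

  # cortisol sampled on the configured grid
  expect_equal(unique(coh$cortisol$time_min), c(-30, 0, 10, 20, 40))

  coh2 <- generate_cohort(d, e)
  expect_identical(coh, coh2)
  coh3 <- generate_cohort(quick_design(seed = 12), e)
  expect_false(identical(coh$trials$rt_ms, coh3$trials$rt_ms))
})

test_that("zero noise reproduces the configured cell means exactly", {
  d <- design_config(n_stress = 2, n_control = 2, trials_per_session = 8,
                     technical_failure_rate = 0, rng_seed = 5)
  e <- null_effects(keep_noise = FALSE)
  coh <- generate_cohort(d, e, components = "trials")
  expect_equal(coh$trials$rt_ms, rep(e$rt_grand_mean, nrow(coh$trials)),
               tolerance = 1e-12)
  expect_equal(coh$trials$mt_ms, rep(e$mt_grand_mean, nrow(coh$trials)),
               tolerance = 1e-12)
  expect_true(all(coh$trials$correct))
  expect_false(any(coh$trials$technical_error))

  # planted rule advantage shows up in cell means with noise off
  e2 <- effect_config(rule_advantage_rt = 120, session_gain_rt = 0,
                      plan_extra_gain_rt = 0, error_rate_rule = 0,
                      error_rate_plan = 0, rmssd_slope_control = 0,
                      rmssd_moderation_slope = 0,
                      noise = list(rt_log_sd = 0, rt_between_log_sd = 0))
  coh2 <- generate_cohort(d, e2, components = "trials")
  m <- tapply(coh2$trials$rt_ms, coh2$trials$approach, mean)
  expect_equal(unname(m["plan"] - m["rule"]), 120)
})

test_that("technical failures occur at the configured rate", {
  d <- design_config(n_stress = 40, n_control = 39, trials_per_session = 64,
                     rng_seed = 99)
  coh <- generate_cohort(d, effect_config(), components = "trials")
  n <- nrow(coh$trials)
  expect_gt(n, 10000)
  p_hat <- mean(coh$trials$technical_error)
  se <- sqrt(0.0189 * (1 - 0.0189) / n)
  expect_lt(abs(p_hat - 0.0189), 3 * se)
})

test_that("planted RT means are recovered by large-sample cell averages", {
  # one participant per group, many trials: empirical means converge on
  # the planted cell means within 3 SE
  d <- design_config(n_stress = 2, n_control = 2, trials_per_session = 10000,
                     technical_failure_rate = 0, rng_seed = 21)
  e <- effect_config(noise = list(rt_between_log_sd = 0, rmssd_react_sd = 0,
                                  rmssd_between_sd = 0))
  coh <- generate_cohort(d, e, components = "trials")
  tr <- coh$trials[coh$trials$participant_id == "P03", ]  # control
  for (s in c("pre", "post")) for (a in c("rule", "plan")) {
    x <- tr$rt_ms[tr$session == s & tr$approach == a]
    planted <- e$rt_grand_mean +
      (if (a == "plan") e$rule_advantage_rt / 2 else -e$rule_advantage_rt / 2) -
      (if (s == "post") e$session_gain_rt else 0) -
      (if (s == "post" && a == "plan") e$plan_extra_gain_rt else 0)
    expect_lt(abs(mean(x) - planted), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("RR series carry planted heart-rate structure and artifacts", {
  d <- quick_design(seed = 31)
  e <- effect_config(noise = list(artifact_fraction = 0))
  coh <- generate_cohort(d, e)
  b <- coh$beats[coh$beats$participant_id == "P01", ]  # stress participant

  hr_phase <- tapply(60000 / b$rr_ms, b$phase, mean)
  expect_gt(hr_phase[["TSST"]], hr_phase[["pre"]])  # planted HR elevation

  # artifact corruption honors the requested fraction and flags beats
  prof_beats <- generate_cohort(quick_design(seed = 31),
                                effect_config(noise = list(artifact_fraction = 0.05)))$beats
  frac <- mean(prof_beats$artifact[prof_beats$participant_id == "P01"])
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.10)

  expect_error(
    generate_cohort(quick_design(),
                    effect_config(noise = list(artifact_fraction = 0.5))),
    "artifact", class = "rpmc_config_error")
})

test_that("zero-noise control cortisol is flat with zero increase area", {
  d <- design_config(n_stress = 2, n_control = 2, rng_seed = 4)
  e <- null_effects(keep_noise = FALSE)
  e$cortisol_peak_delta_stress <- 0
  coh <- generate_cohort(d, e, components = "cortisol")
  ctl <- coh$cortisol[coh$cortisol$participant_id == "P03", ]
  expect_equal(var(ctl$cortisol_nmol_l), 0)
  ts <- data.frame(time_min = ctl$time_min, value = ctl$cortisol_nmol_l,
                   label = ctl$label)
  expect_equal(auc_increase(ts, c("t2", "t5"))$auc_i, 0)

  # stress participant with a positive pulse: AUC_I over t2-t5 positive,
  # matching a hand trapezoid of the configured trajectory
  e2 <- null_effects(keep_noise = FALSE)
  e2$cortisol_peak_delta_stress <- 8
  coh2 <- generate_cohort(d, e2, components = "cortisol")
  st <- coh2$cortisol[coh2$cortisol$participant_id == "P01", ]
  ts2 <- data.frame(time_min = st$time_min, value = st$cortisol_nmol_l,
                    label = st$label)
  got <- auc_increase(ts2, c("t2", "t5"))$auc_i
  v <- st$cortisol_nmol_l[2:5]; tt <- st$time_min[2:5]
  hand <- sum(diff(tt) * (head(v, -1) + v[-1]) / 2) - v[1] * (tt[4] - tt[1])
  expect_equal(got, hand, tolerance = 1e-12)
  expect_gt(got, 0)
})

test_that("a high-error participant is flagged for exclusion downstream", {
  d <- design_config(n_stress = 2, n_control = 2, trials_per_session = 32,
                     technical_failure_rate = 0, rng_seed = 8)
  e <- effect_config(error_rate_plan = 0.5, error_rate_rule = 0.5)
  coh <- generate_cohort(d, e, components = "trials")
  ex <- exclude_participants(coh$trials)
  expect_true(length(ex$excluded) >= 1)
})

test_that("marker summary simulator is deterministic and group-structured", {
  s1 <- simulate_marker_summaries(19, 17, seed = 3)
  s2 <- simulate_marker_summaries(19, 17, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 36)
  expect_setequal(unique(s1$group01), c(0, 1))
  # stress group shows RMSSD withdrawal (negative increase area) on average
  expect_lt(mean(s1$auc_lnrmssd[s1$group == "stress"]),
            mean(s1$auc_lnrmssd[s1$group == "control"]))
})
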