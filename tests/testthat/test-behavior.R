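# Trial filtering, generalized ESD, participant exclusion, BI-Scores
# and derived summaries.

test_that("technical-error filtering drops flagged trials and reports counts", {
  tr <- trials_df("A", "pre", "rule", rt_ms = rep(500, 100))
  res <- filter_trials(tr)
  expect_equal(res$report$n_technical, 0)
  expect_identical(res$trials, tr)

  tr$technical_error[c(3, 40, 77)] <- TRUE
  res2 <- filter_trials(tr)
  expect_equal(res2$report$n_technical, 3)
  expect_equal(nrow(res2$trials), 97)
})

test_that("ESD flags the planted outlier in the textbook example", {
  x <- c(10, 10.1, 9.9, 10.05, 50)
  mask <- esd_filter(x, alpha = 0.05, max_outliers = 1)
  expect_equal(which(mask), 5)

  # hand-computed first round: R1 and lambda1
  R1 <- max(abs(x - mean(x))) / sd(x)
  tv <- qt(1 - 0.05 / (2 * 5), 3)
  lambda1 <- 4 * tv / sqrt((3 + tv^2) * 5)
  expect_gt(R1, lambda1)

  expect_equal(sum(esd_filter(rep(10, 8), max_outliers = 2)), 0)
  expect_error(esd_filter(c(1, 2, 3, 4)), class = "rpmc_input_error")
  expect_error(esd_filter(1:10, max_outliers = 5), class = "rpmc_input_error")
})

test_that("ESD mask equals the reference transliteration on contaminated data", {
  withr::with_seed(33, {
    for (i in 1:100) {
      n <- sample(20:60, 1)
      x <- rnorm(n, 500, 40)
      n_out <- sample(0:3, 1)
      if (n_out > 0)
        x[sample(n, n_out)] <- 500 + sample(c(-1, 1), n_out, TRUE) *
          runif(n_out, 200, 500)
      k <- 5
      expect_identical(esd_filter(x, 0.05, k), esd_oracle(x, 0.05, k))
    }
  })
})

test_that("ESD mask is permutation-equivariant and scale-invariant", {
  withr::with_seed(17, {
    x <- c(rnorm(30, 100, 5), 160, 40)
    perm <- sample(length(x))
  })
  m <- esd_filter(x, max_outliers = 4)
  expect_identical(esd_filter(x[perm], max_outliers = 4), m[perm])
  expect_identical(esd_filter(10 * x + 3, max_outliers = 4), m)
})

test_that("participant exclusion uses a strict 20% threshold", {
  mk <- function(id, n_err) {
    correct <- rep(TRUE, 40); if (n_err > 0) correct[seq_len(n_err)] <- FALSE
    trials_df(id, "pre", "rule", rt_ms = rep(500, 40), correct = correct)
  }
  tr <- rbind(mk("good", 0), mk("borderline", 8), mk("bad", 10))
  res <- exclude_participants(tr, error_threshold = 0.20)
  expect_identical(res$excluded, "bad")              # 25% out
  expect_true("borderline" %in% res$trials$participant_id)  # exactly 20% kept
  res2 <- exclude_participants(rbind(mk("a", 0), mk("b", 0)))
  expect_length(res2$excluded, 0)
})

test_that("BI-Scores reproduce the two-cell closed form", {
  # two cells: PC {1.0, 0.5}, mean correct RT {500, 700}
  tr <- rbind(
    trials_df("A", "pre", "rule", rt_ms = c(500, 500), correct = c(TRUE, TRUE)),
    trials_df("A", "pre", "plan", rt_ms = c(700, 999), correct = c(TRUE, FALSE)))
  cells <- bi_scores(tr)
  cells <- cells[order(cells$approach, decreasing = TRUE), ]  # rule first
  expect_equal(cells$prop_correct, c(1.0, 0.5))
  expect_equal(cells$mean_rt_ms, c(500, 700))
  expect_equal(cells$bi, c(sqrt(2), -sqrt(2)), tolerance = 1e-9)
  expect_equal(round(cells$bi, 3), c(1.414, -1.414))
})

test_that("BI standardization is pooled with mean 0 / SD 1 and errors when degenerate", {
  d <- quick_design(seed = 61)
  coh <- generate_cohort(d, effect_config(), components = "trials")
  flagged <- flag_outlier_trials(filter_trials(coh$trials)$trials)
  cells <- bi_scores(flagged)
  z_pc <- (cells$prop_correct - mean(cells$prop_correct)) / sd(cells$prop_correct)
  expect_equal(mean(z_pc), 0, tolerance = 1e-12)
  expect_equal(sd(z_pc), 1, tolerance = 1e-12)
  expect_equal(mean(cells$bi), 0, tolerance = 1e-12)

  # all cells identical -> zero pooled variance -> documented error
  tr <- rbind(trials_df("A", "pre", "rule", rt_ms = rep(500, 4)),
              trials_df("A", "pre", "plan", rt_ms = rep(500, 4)))
  expect_error(bi_scores(tr), class = "rpmc_degenerate_error")
})

test_that("BI decreases in RT at fixed accuracy and balances speed-accuracy trades", {
  base <- rbind(
    trials_df("A", "pre", "rule", rt_ms = rep(500, 10)),
    trials_df("A", "pre", "plan", rt_ms = rep(600, 10)),
    trials_df("B", "pre", "rule", rt_ms = rep(550, 10),
              correct = c(rep(TRUE, 9), FALSE)),
    trials_df("B", "pre", "plan", rt_ms = rep(650, 10),
              correct = c(rep(TRUE, 8), rep(FALSE, 2))))
  cells <- bi_scores(base)
  slower <- base
  slower$rt_ms[slower$participant_id == "A" & slower$approach == "plan"] <- 700
  cells2 <- bi_scores(slower)
  pick <- function(cl) cl$bi[cl$participant_id == "A" & cl$approach == "plan"]
  expect_lt(pick(cells2), pick(cells))

  # matched z-offsets in speed and accuracy cancel out: construct two
  # cells symmetric around the pooled means in both components
  tr <- rbind(
    trials_df("C", "pre", "rule", rt_ms = rep(480, 10)),                 # fast, perfect
    trials_df("C", "pre", "plan", rt_ms = rep(520, 10),
              correct = c(rep(TRUE, 9), FALSE)))                         # slow, less accurate
  cl <- bi_scores(tr)
  # both components are z-scored over the same two cells, so the faster
  # but less accurate cell and the slower but more accurate cell sit at
  # equal-magnitude opposite BIS
  expect_equal(sum(cl$bi), 0, tolerance = 1e-9)
})

test_that("summaries satisfy the advantage and change identities", {
  d <- quick_design(seed = 71)
  coh <- generate_cohort(d, effect_config(), components = "trials")
  scored <- score_trials(coh$trials)
  s <- scored$summaries
  expect_equal(s$advantage_pre, s$bi_pre_rule - s$bi_pre_plan)
  expect_equal(s$advantage_post, s$bi_post_rule - s$bi_post_plan)
  expect_equal(s$change_rule, s$bi_post_rule - s$bi_pre_rule)
  expect_equal(s$change_plan, s$bi_post_plan - s$bi_pre_plan)

  # hand-built cells: advantage and zero-change fixtures
  cells <- data.frame(
    participant_id = "Z", group = "control",
    session = rep(c("pre", "post"), each = 2),
    approach = rep(c("rule", "plan"), 2),
    n_trials_used = 8, prop_correct = 1,
    mean_rt_ms = 500, mean_mt_ms = 700,
    bi = c(1, 0, 1, 0), stringsAsFactors = FALSE)
  s2 <- derive_summaries(cells)
  expect_equal(s2$advantage_pre, 1)
  expect_equal(s2$change_rule, 0)
  expect_equal(s2$change_plan, 0)

  # a participant missing a cell is dropped with a warning
  expect_warning(s3 <- derive_summaries(cells[-1, ]), "incomplete")
  expect_equal(nrow(s3), 0)
})

test_that("a planted session x approach interaction widens plan-based change", {
  d <- design_config(n_stress = 6, n_control = 6, trials_per_session = 32,
                     rng_seed = 81)
  e <- effect_config(plan_extra_gain_rt = 80,
                     rmssd_slope_control = 0, rmssd_moderation_slope = 0)
  coh <- generate_cohort(d, e, components = "trials")
  scored <- score_trials(coh$trials)
  expect_gt(mean(scored$summaries$change_plan),
            mean(scored$summaries$change_rule))
})
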