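# Pipeline orchestration: generate -> extract -> score -> test, with
# CSV/JSON artifacts so any later stage can be resumed from disk.

analysis_defaults <- function() {
  list(alpha = 0.05,
       esd_alpha = 0.05,
       esd_max_frac = 0.2,
       error_threshold = 0.20,
       deviation_threshold = 0.25,
       hr_log = TRUE,
       welch_markers = "lnRMSSD",
       bonferroni_family = 2,
       lilliefors = TRUE)
}

#' Load and validate a pipeline run configuration
#'
#' YAML (or JSON, a YAML subset) with up to four blocks: `design`,
#' `effects` (with optional `noise` sub-block), `analysis` and `out`.
#' Unknown keys raise a configuration error naming the key; every
#' analysis constant (windows, thresholds, alpha, ESD parameters) has
#' the reference defaults.
#'
#' @param path path to a YAML/JSON config file.
#' @return List with validated `design`, `effects`, `analysis`, `out`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    stop_config("config", sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_run_config(raw)
}

build_run_config <- function(raw) {
  allowed <- c("design", "effects", "analysis", "out")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop_config(unknown[1], "unknown top-level config key")

  check_keys <- function(block, fn, label) {
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra))
      stop_config(paste0(label, "$", extra[1]), "unknown config key")
  }
  des <- raw$design %||% list()
  if (!is.null(des$phase_minutes)) des$phase_minutes <- unlist(des$phase_minutes)
  check_keys(des, design_config, "design")
  design <- do.call(design_config, des)

  eff <- raw$effects %||% list()
  check_keys(eff, effect_config, "effects")
  effects <- do.call(effect_config, eff)

  ana <- raw$analysis %||% list()
  extra <- setdiff(names(ana), names(analysis_defaults()))
  if (length(extra))
    stop_config(paste0("analysis$", extra[1]), "unknown config key")
  analysis <- modifyList(analysis_defaults(), ana)

  list(design = design, effects = effects, analysis = analysis,
       out = raw$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- marker extraction --------------------------------------------------

#' Extract HR / ln-RMSSD / ln-cortisol marker timelines for a cohort
#'
#' Cleans each participant's RR series ([clean_rr()]), computes the
#' nine-interval HR and ln-RMSSD timelines ([interval_markers()]), and
#' ln-transforms the cortisol samples into an `lnCortisol` series.
#'
#' @param beats long RR data frame (`participant_id, beat_time_s,
#'   rr_ms, ...`).
#' @param cortisol long cortisol data frame (`participant_id, label,
#'   time_min, cortisol_nmol_l`).
#' @param design an [design_config()] object.
#' @param deviation_threshold artifact-flagging threshold for
#'   [clean_rr()].
#' @return List with `markers` (long data frame `participant_id,
#'   marker, label, time_min, value`) and `cleaning` (per-participant
#'   cleaning reports).
#' @export
extract_markers <- function(beats, cortisol, design = design_config(),
                            deviation_threshold = 0.25) {
  marker_rows <- list()
  cleaning <- list()
  for (pid in unique(beats$participant_id)) {
    pb <- beats[beats$participant_id == pid, , drop = FALSE]
    cl <- clean_rr(pb, deviation_threshold = deviation_threshold)
    cleaning[[pid]] <- cl$report
    mk <- interval_markers(cl$beats, design = design)
    mk$participant_id <- pid
    marker_rows[[length(marker_rows) + 1L]] <- mk
  }
  for (pid in unique(cortisol$participant_id)) {
    pc <- cortisol[cortisol$participant_id == pid, , drop = FALSE]
    marker_rows[[length(marker_rows) + 1L]] <- data.frame(
      marker = "lnCortisol", label = pc$label, time_min = pc$time_min,
      value = log(pc$cortisol_nmol_l), participant_id = pid,
      stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, marker_rows)
  markers <- markers[, c("participant_id", "marker", "label",
                         "time_min", "value")]
  rownames(markers) <- NULL
  list(markers = markers, cleaning = cleaning)
}

# -- scoring ------------------------------------------------------------

#' Score behavioural trials into cells and participant summaries
#'
#' Runs the behavioural chain: technical-error filtering, per-cell
#' generalized-ESD outlier flagging, participant exclusion (error rate
#' strictly above threshold), Balanced Integration Scores, and the
#' advantage/change summaries.
#'
#' @param trials trial data frame.
#' @param analysis analysis options list (see [load_run_config()]).
#' @return List: `cells`, `summaries`, `excluded`, `log` (trial
#'   accounting: counts per filter step).
#' @export
score_trials <- function(trials, analysis = analysis_defaults()) {
  ft <- filter_trials(trials)
  flagged <- flag_outlier_trials(ft$trials, alpha = analysis$esd_alpha,
                                 max_frac = analysis$esd_max_frac)
  ex <- exclude_participants(flagged,
                             error_threshold = analysis$error_threshold)
  cells <- bi_scores(ex$trials)
  summaries <- derive_summaries(cells)
  list(cells = cells, summaries = summaries, excluded = ex$excluded,
       log = list(n_trials_in = ft$report$n_in,
                  n_technical_removed = ft$report$n_technical,
                  n_rt_outliers = sum(flagged$rt_outlier),
                  n_mt_outliers = sum(flagged$mt_outlier),
                  n_participants_excluded = length(ex$excluded),
                  excluded_ids = ex$excluded))
}

# -- analysis -----------------------------------------------------------

auc_wide <- function(auc) {
  pick <- function(mk) {
    s <- auc[auc$marker == mk, c("participant_id", "auc_i")]
    names(s)[2] <- paste0("auc_", tolower(mk))
    s
  }
  w <- Reduce(function(x, y) merge(x, y, by = "participant_id"),
              lapply(unique(auc$marker), pick))
  names(w) <- sub("auc_lncortisol", "auc_lncort", names(w))
  w
}

#' Inferential analysis of a scored cohort
#'
#' Produces the full report: normality checks of the AUC_I markers and
#' change scores, mixed ANOVAs of BI-Scores and movement time, paired
#' t-tests of the rule-based efficiency advantage change (whole sample
#' and per group, Bonferroni family of 2), independent-samples group
#' comparisons of each AUC_I marker (control vs stress; Welch where
#' configured), and the two 9-predictor moderated change regressions.
#'
#' @param scored result of [score_trials()].
#' @param auc AUC table from [cohort_auc()].
#' @param participants participant table (`participant_id, group, age,
#'   bmi`).
#' @param analysis analysis options list.
#' @return List of class `rpmc_analysis`.
#' @export
analyze_cohort <- function(scored, auc, participants,
                           analysis = analysis_defaults()) {
  summ <- scored$summaries
  cells <- scored$cells

  anova_bi <- mixed_anova(cells, dv = "bi")
  anova_mt <- mixed_anova(cells, dv = "mean_mt_ms")

  adv_all <- t_test(summ$advantage_post, summ$advantage_pre, kind = "paired")
  grp <- function(g) summ$group == g
  adv_stress <- t_test(summ$advantage_post[grp("stress")],
                       summ$advantage_pre[grp("stress")],
                       kind = "paired", m = analysis$bonferroni_family)
  adv_control <- t_test(summ$advantage_post[grp("control")],
                        summ$advantage_pre[grp("control")],
                        kind = "paired", m = analysis$bonferroni_family)

  auc <- auc[auc$participant_id %in% summ$participant_id, , drop = FALSE]
  auc <- merge(auc, participants[, c("participant_id", "group")],
               by = "participant_id")
  marker_tests <- list()
  normality <- list()
  for (mk in unique(auc$marker)) {
    x <- auc[auc$marker == mk, ]
    kind <- if (mk %in% analysis$welch_markers) "welch" else "independent"
    marker_tests[[mk]] <- t_test(x$auc_i[x$group == "control"],
                                 x$auc_i[x$group == "stress"], kind = kind)
    normality[[paste0("auc_i_", mk)]] <-
      ks_normality(x$auc_i, lilliefors = analysis$lilliefors)
  }
  normality$change_plan <- ks_normality(summ$change_plan,
                                        lilliefors = analysis$lilliefors)
  normality$change_rule <- ks_normality(summ$change_rule,
                                        lilliefors = analysis$lilliefors)

  w <- auc_wide(auc[, c("participant_id", "marker", "auc_i")])
  reg_data <- merge(merge(summ, w, by = "participant_id"),
                    participants[, c("participant_id", "age", "bmi")],
                    by = "participant_id")
  reg_data$group01 <- as.integer(reg_data$group == "stress")
  regression_plan <- fit_change_model(reg_data, dv = "change_plan")
  regression_rule <- fit_change_model(reg_data, dv = "change_rule")

  structure(list(
    anova_bi = anova_bi,
    anova_mt = anova_mt,
    advantage_tests = list(all = adv_all, stress = adv_stress,
                           control = adv_control),
    marker_tests = marker_tests,
    normality = normality,
    regression_plan = regression_plan,
    regression_rule = regression_rule,
    change_means = list(
      plan = mean(summ$change_plan), plan_sd = sd(summ$change_plan),
      rule = mean(summ$change_rule), rule_sd = sd(summ$change_rule))
  ), class = "rpmc_analysis")
}

# -- full run -----------------------------------------------------------

#' Run the full pipeline
#'
#' Generates (or accepts) a cohort, extracts markers, computes AUC_I
#' stress markers, scores behaviour and runs the inferential layer.
#' The same config and seed reproduce the report bit-identically.
#'
#' @param config a config list (as from [load_run_config()]), a path to
#'   a YAML/JSON config file, or `NULL` for all defaults.
#' @param seed optional seed overriding `design$rng_seed`.
#' @param out_dir optional directory for the CSV + JSON artifact bundle.
#' @param cohort optional pre-built `rpmc_cohort` (skips generation).
#' @return List of class `rpmc_report` with the cohort metadata, marker
#'   and score tables, the analysis block, the run log and the seed.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL,
                         cohort = NULL) {
  cfg <- if (is.null(config)) build_run_config(list())
  else if (is.character(config)) load_run_config(config)
  else build_run_config(config)
  if (!is.null(seed)) {
    des <- unclass(cfg$design)
    des$rng_seed <- as.integer(seed)
    cfg$design <- do.call(design_config, des)
  }
  if (is.null(out_dir)) out_dir <- cfg$out

  if (is.null(cohort)) cohort <- generate_cohort(cfg$design, cfg$effects)
  ext <- extract_markers(cohort$beats, cohort$cortisol, cfg$design,
                         deviation_threshold = cfg$analysis$deviation_threshold)
  auc <- cohort_auc(ext$markers, hr_log = cfg$analysis$hr_log)
  scored <- score_trials(cohort$trials, cfg$analysis)
  analysis <- analyze_cohort(scored, auc, cohort$participants, cfg$analysis)

  report <- structure(list(
    meta = list(
      package = "rpmcstress",
      version = as.character(utils::packageVersion("rpmcstress")),
      seed = cfg$design$rng_seed,
      n_stress = cfg$design$n_stress,
      n_control = cfg$design$n_control,
      n_analyzed = nrow(scored$summaries)),
    config = list(design = unclass(cfg$design),
                  effects = unclass(cfg$effects),
                  analysis = cfg$analysis),
    log = c(scored$log,
            list(cleaning = ext$cleaning)),
    auc = auc,
    cells = scored$cells,
    summaries = scored$summaries,
    analysis = analysis
  ), class = "rpmc_report")

  if (!is.null(out_dir)) write_report_bundle(report, cohort, ext$markers,
                                             out_dir)
  report
}

# -- artifacts ----------------------------------------------------------

write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) if (!is.null(d))
    write.csv(d, file.path(dir, f), row.names = FALSE)
  tr <- cohort$trials
  if (!is.null(tr)) {
    out <- tr[, c("participant_id", "group", "session", "approach",
                  "trial_index", "rt_ms", "mt_ms", "correct",
                  "technical_error")]
    write.csv(out, file.path(dir, "trials.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$beats))
    w(cohort$beats[, c("participant_id", "beat_time_s", "rr_ms", "phase")],
      "rr.csv")
  if (!is.null(cohort$cortisol))
    w(cohort$cortisol[, c("participant_id", "time_min", "cortisol_nmol_l")],
      "cortisol.csv")
  w(cohort$participants, "participants.csv")
  jsonlite::write_json(cohort$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_report_bundle <- function(report, cohort, markers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(cohort, dir)
  write.csv(markers, file.path(dir, "markers.csv"), row.names = FALSE)
  write.csv(report$auc, file.path(dir, "auc.csv"), row.names = FALSE)
  write.csv(report$cells, file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(report$summaries, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$analysis$anova_bi),
            file.path(dir, "anova_bi.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$analysis$anova_mt),
            file.path(dir, "anova_mt.csv"), row.names = FALSE)
  write.csv(report$analysis$regression_plan$coefficients,
            file.path(dir, "regression_plan.csv"), row.names = FALSE)
  write.csv(report$analysis$regression_rule$coefficients,
            file.path(dir, "regression_rule.csv"), row.names = FALSE)
  jsonlite::write_json(report_to_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

# JSON-friendly view of the report (schema_version marks the layout).
report_to_json <- function(report) {
  an <- report$analysis
  tst <- function(t) t[c("statistic", "df", "p", "p_adjusted", "kind")]
  list(
    schema_version = "1.0",
    meta = report$meta,
    log = report$log,
    anova_bi = as.data.frame(an$anova_bi),
    anova_mt = as.data.frame(an$anova_mt),
    advantage_tests = lapply(an$advantage_tests, tst),
    marker_tests = lapply(an$marker_tests, tst),
    normality = lapply(an$normality, tst),
    regression_plan = unclass_regression(an$regression_plan),
    regression_rule = unclass_regression(an$regression_rule),
    change_means = an$change_means
  )
}

unclass_regression <- function(r) {
  list(coefficients = r$coefficients, F = r$F, df1 = r$df1, df2 = r$df2,
       p = r$p, r_squared = r$r_squared, durbin_watson = r$durbin_watson,
       vif = as.list(r$vif), n = r$n)
}

#' @export
print.rpmc_report <- function(x, ...) {
  cat(sprintf("RPMC stress pipeline report (seed %d): %d + %d participants, %d analyzed\n",
              x$meta$seed, x$meta$n_stress, x$meta$n_control,
              x$meta$n_analyzed))
  cat("\nBI-Score mixed ANOVA:\n")
  print(as.data.frame(x$analysis$anova_bi), digits = 3)
  cat(sprintf("\nAdvantage change (whole sample): t(%d) = %.2f, p = %.4g\n",
              x$analysis$advantage_tests$all$df,
              x$analysis$advantage_tests$all$statistic,
              x$analysis$advantage_tests$all$p))
  cat(sprintf("Plan-based change regression: F(%d,%d) = %.2f, p = %.4g, R^2 = %.3f\n",
              x$analysis$regression_plan$df1, x$analysis$regression_plan$df2,
              x$analysis$regression_plan$F, x$analysis$regression_plan$p,
              x$analysis$regression_plan$r_squared))
  invisible(x)
}
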