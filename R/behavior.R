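# Behavioural scoring: trial filtering, generalized-ESD outlier
# removal, participant exclusion, Balanced Integration Scores and the
# derived efficiency-advantage / change summaries.

#' Drop technically failed trials
#'
#' @param trials trial data frame (dialect of [generate_trials()]).
#' @return List with `trials` (surviving rows) and `report`
#'   (`n_in`, `n_technical`, `n_out`).
#' @export
filter_trials <- function(trials) {
  drop <- trials$technical_error
  list(trials = trials[!drop, , drop = FALSE],
       report = list(n_in = nrow(trials),
                     n_technical = sum(drop),
                     n_out = sum(!drop)))
}

#' Generalized extreme studentized deviate (ESD) outlier mask
#'
#' Rosner's generalized ESD test for up to `max_outliers` outliers in a
#' roughly normal sample. Iteratively, the most extreme studentized
#' deviation `R_i = max |x - mean| / sd` is computed and its point
#' removed; `R_i` is compared against the critical value
#' `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))`
#' with `t = qt(1 - alpha / (2 * (n - i + 1)), n - i - 1)`. The number
#' of outliers is the largest `i` with `R_i > lambda_i`; that point and
#' all more extreme ones are flagged.
#'
#' @param values numeric vector, length at least 5.
#' @param alpha significance level of the test (default 0.05).
#' @param max_outliers maximum number of outliers tested for; must be
#'   below `length(values) / 2`.
#' @return Logical mask, `TRUE` marking outliers. A zero-variance
#'   sample yields an all-`FALSE` mask.
#' @export
esd_filter <- function(values, alpha = 0.05, max_outliers = 1L) {
  n <- length(values)
  if (n < 5)
    stop_input("ESD test requires at least 5 values")
  if (max_outliers < 1 || max_outliers >= n / 2)
    stop_input("max_outliers must be in [1, n/2)")
  mask <- rep(FALSE, n)
  remaining <- seq_len(n)
  removed <- integer(0)
  R <- lambda <- rep(NA_real_, max_outliers)
  for (i in seq_len(max_outliers)) {
    x <- values[remaining]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    ni <- n - i + 1                      # sample size at step i
    p <- 1 - alpha / (2 * ni)
    tcrit <- qt(p, ni - 2)
    lambda[i] <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    removed <- c(removed, remaining[j])
    remaining <- remaining[-j]
  }
  n_out <- 0L
  for (i in seq_along(R))
    if (is.finite(R[i]) && R[i] > lambda[i]) n_out <- i
  if (n_out > 0) mask[removed[seq_len(n_out)]] <- TRUE
  mask
}

#' Flag response- and movement-time outliers per cell
#'
#' Applies [esd_filter()] within each participant x session x approach
#' cell, separately to response times and movement times. Cells with
#' fewer than 5 trials are left unflagged. `max_outliers` is 20% of the
#' cell size (at least 1).
#'
#' @param trials filtered trial data frame.
#' @param alpha ESD significance level.
#' @param max_frac maximum outlier fraction tested per cell.
#' @return `trials` with logical columns `rt_outlier`, `mt_outlier` and
#'   `outlier` (their union) filled in.
#' @export
flag_outlier_trials <- function(trials, alpha = 0.05, max_frac = 0.2) {
  trials$rt_outlier <- FALSE
  trials$mt_outlier <- FALSE
  key <- interaction(trials$participant_id, trials$session, trials$approach,
                     drop = TRUE)
  for (cell in levels(key)) {
    idx <- which(key == cell)
    if (length(idx) < 5) next
    k <- max(1L, floor(max_frac * length(idx)))
    k <- min(k, length(idx) %/% 2 - 1 + (length(idx) %% 2))  # keep < n/2
    if (k < 1) next
    trials$rt_outlier[idx] <- esd_filter(trials$rt_ms[idx], alpha, k)
    trials$mt_outlier[idx] <- esd_filter(trials$mt_ms[idx], alpha, k)
  }
  trials$outlier <- trials$rt_outlier | trials$mt_outlier
  trials
}

#' Exclude participants with excessive error rates
#'
#' Participants whose overall error proportion (across all retained
#' movement-selection trials) is strictly greater than `error_threshold`
#' are removed entirely, mirroring the task-comprehension exclusion
#' rule ("more than 20% errors"). A participant at exactly the
#' threshold is retained.
#'
#' @param trials technically filtered trial data frame.
#' @param error_threshold exclusion threshold (default 0.20).
#' @return List with `trials` (survivors) and `excluded`
#'   (character vector of participant ids).
#' @export
exclude_participants <- function(trials, error_threshold = 0.20) {
  err <- tapply(!trials$correct, trials$participant_id, mean)
  excluded <- names(err)[err > error_threshold]
  list(trials = trials[!(trials$participant_id %in% excluded), , drop = FALSE],
       excluded = as.character(excluded))
}

#' Balanced Integration Scores per cell
#'
#' For each participant x session x approach cell, computes the
#' proportion of correct responses (PC) and the mean response time of
#' correct, non-outlier trials (RT), then z-standardizes both over the
#' pooled set of all cells of all analyzed participants (sample SD,
#' n - 1) and scores `BIS = z(PC) - z(RT)`. Higher is better; the equal
#' weighting of speed and accuracy controls for speed-accuracy
#' tradeoffs. Movement-time cell means (correct, non-outlier trials)
#' are carried alongside.
#'
#' @param trials outlier-flagged trial data frame
#'   (see [flag_outlier_trials()]).
#' @return Data frame with one row per cell: `participant_id, group,
#'   session, approach, n_trials_used, prop_correct, mean_rt_ms,
#'   mean_mt_ms, bi`.
#' @export
bi_scores <- function(trials) {
  if (is.null(trials$rt_outlier)) trials$rt_outlier <- FALSE
  if (is.null(trials$mt_outlier)) trials$mt_outlier <- FALSE
  split_key <- list(trials$participant_id, trials$session, trials$approach)
  cells <- do.call(rbind, by(trials, split_key, function(d) {
    use_rt <- d$correct & !d$rt_outlier
    use_mt <- d$correct & !d$mt_outlier
    data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      session = d$session[1], approach = d$approach[1],
      n_trials_used = sum(!d$rt_outlier),
      prop_correct = mean(d$correct[!d$rt_outlier]),
      mean_rt_ms = if (any(use_rt)) mean(d$rt_ms[use_rt]) else NA_real_,
      mean_mt_ms = if (any(use_mt)) mean(d$mt_ms[use_mt]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  if (any(!is.finite(cells$mean_rt_ms)))
    warning("cells without correct trials are carried as missing")

  z <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_rpmc("rpmc_degenerate_error",
                "zero pooled variance: BI standardization undefined")
    (x - mean(x, na.rm = TRUE)) / s
  }
  cells$bi <- z(cells$prop_correct) - z(cells$mean_rt_ms)
  cells
}

#' Per-participant efficiency-advantage and change summaries
#'
#' Collapses the four BI cells per participant into the derived
#' quantities of the analysis: the rule-based efficiency advantage
#' per session (`bi(rule, s) - bi(plan, s)`) and the pre-to-post change
#' per approach (`bi(a, post) - bi(a, pre)`), alongside movement-time
#' cell means. Participants lacking any of the four cells are dropped
#' with a warning.
#'
#' @param cells cell-score data frame from [bi_scores()].
#' @return Data frame with one row per participant: BI per cell,
#'   `advantage_pre`, `advantage_post`, `change_rule`, `change_plan`,
#'   and the four movement-time means.
#' @export
derive_summaries <- function(cells) {
  pick <- function(d, s, a, col) {
    v <- d[[col]][d$session == s & d$approach == a]
    if (length(v) == 1) v else NA_real_
  }
  out <- do.call(rbind, by(cells, cells$participant_id, function(d) {
    row <- data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      bi_pre_rule = pick(d, "pre", "rule", "bi"),
      bi_pre_plan = pick(d, "pre", "plan", "bi"),
      bi_post_rule = pick(d, "post", "rule", "bi"),
      bi_post_plan = pick(d, "post", "plan", "bi"),
      mt_pre_rule = pick(d, "pre", "rule", "mean_mt_ms"),
      mt_pre_plan = pick(d, "pre", "plan", "mean_mt_ms"),
      mt_post_rule = pick(d, "post", "rule", "mean_mt_ms"),
      mt_post_plan = pick(d, "post", "plan", "mean_mt_ms"),
      stringsAsFactors = FALSE)
    row$advantage_pre <- row$bi_pre_rule - row$bi_pre_plan
    row$advantage_post <- row$bi_post_rule - row$bi_post_plan
    row$change_rule <- row$bi_post_rule - row$bi_pre_rule
    row$change_plan <- row$bi_post_plan - row$bi_pre_plan
    row
  }))
  rownames(out) <- NULL
  incomplete <- !complete.cases(
    out[, c("bi_pre_rule", "bi_pre_plan", "bi_post_rule", "bi_post_plan")])
  if (any(incomplete)) {
    warning(sprintf("dropping %d participant(s) with incomplete BI cells: %s",
                    sum(incomplete),
                    paste(out$participant_id[incomplete], collapse = ", ")))
    out <- out[!incomplete, , drop = FALSE]
  }
  out
}
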