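# Inferential layer: mixed-design repeated-measures ANOVA, t-tests,
# normality checks, and the moderated regression models with
# diagnostics.

#' 2 x 2 x 2 mixed-design repeated-measures ANOVA
#'
#' One between-subjects factor (group) and two within-subjects factors
#' (session, approach), one observation per cell. Fit via the standard
#' split-plot error strata (`Error(participant/(session*approach))`);
#' with a single between factor and complete within cells the
#' partitioning is Type-III-equivalent even for unbalanced groups.
#' Sphericity holds by construction for 2-level factors, so the
#' Mauchly check is reported as passing.
#'
#' @param cells data frame with columns `participant_id, group,
#'   session, approach` and the dependent variable.
#' @param dv name of the dependent-variable column (e.g. `"bi"`).
#' @return Data frame of class `rpmc_anova` with one row per effect:
#'   `effect, df1, df2, ss, F, p`, plus attributes `ss_total` and
#'   `sphericity`.
#' @export
mixed_anova <- function(cells, dv = "bi") {
  d <- data.frame(
    participant = factor(cells$participant_id),
    group = factor(cells$group),
    session = factor(cells$session, levels = c("pre", "post")),
    approach = factor(cells$approach, levels = c("rule", "plan")),
    y = cells[[dv]])
  counts <- table(d$participant)
  bad <- names(counts)[counts != 4]
  missing_y <- unique(as.character(d$participant[!is.finite(d$y)]))
  bad <- union(bad, missing_y)
  if (length(bad))
    stop_input(paste("incomplete cells for participant(s):",
                     paste(sort(bad), collapse = ", ")),
               participants = bad)
  if (nlevels(d$group) != 2)
    stop_input("exactly two groups are required")

  # a constant response carries no variance to partition: all F = 0
  if (var(d$y) < 1e-20 * (abs(mean(d$y)) + 1)^2) {
    n <- nlevels(d$participant)
    res <- data.frame(
      effect = c("group", "session", "group x session", "approach",
                 "group x approach", "session x approach",
                 "group x session x approach"),
      df1 = 1L, df2 = n - 2L, ss = 0, F = 0, p = 1,
      stringsAsFactors = FALSE)
    attr(res, "ss_total") <- 0
    attr(res, "ss_error") <- 0
    attr(res, "sphericity") <- "satisfied by construction (2-level factors)"
    class(res) <- c("rpmc_anova", "data.frame")
    return(res)
  }

  fit <- aov(y ~ group * session * approach +
               Error(participant / (session * approach)), data = d)
  rows <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    resid_i <- grep("^Residuals", trimws(terms))
    df2 <- tab[resid_i, "Df"]
    ms_err <- tab[resid_i, "Mean Sq"]
    for (i in setdiff(seq_along(terms), resid_i)) {
      ss <- tab[i, "Sum Sq"]
      Fv <- if (ss <= 1e-300 && ms_err <= 1e-300) 0 else tab[i, "F value"]
      pv <- if (ss <= 1e-300 && ms_err <= 1e-300) 1 else tab[i, "Pr(>F)"]
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", trimws(terms[i])),
        df1 = tab[i, "Df"], df2 = df2, ss = ss,
        F = Fv, p = pv, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      effect = paste0("residuals(", df2, ")"), df1 = df2, df2 = NA,
      ss = tab[resid_i, "Sum Sq"], F = NA, p = NA, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  res <- out[!grepl("^residuals", out$effect), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "ss_total") <- sum(out$ss)
  attr(res, "ss_error") <- sum(out$ss[grepl("^residuals", out$effect)])
  attr(res, "sphericity") <- "satisfied by construction (2-level factors)"
  class(res) <- c("rpmc_anova", "data.frame")
  res
}

#' t-tests with optional Bonferroni correction
#'
#' Wraps the paired, pooled-variance independent, and Welch forms.
#' Welch degrees of freedom follow Welch-Satterthwaite and may be
#' fractional. Bonferroni adjustment multiplies p by the family size
#' `m`, capped at 1.
#'
#' @param a,b numeric samples (`b` against `mu` is a one-sample test if
#'   `NULL`).
#' @param kind `"paired"`, `"independent"` (pooled variance) or
#'   `"welch"`.
#' @param mu null value (default 0).
#' @param m Bonferroni family size (default 1 = no correction).
#' @return List of class `rpmc_test`: `statistic, df, p, p_adjusted,
#'   kind`.
#' @export
t_test <- function(a, b = NULL, kind = c("paired", "independent", "welch"),
                   mu = 0, m = 1) {
  kind <- match.arg(kind)
  if (kind == "paired") {
    if (is.null(b)) {
      d <- a
    } else {
      if (length(a) != length(b))
        stop_input("paired samples must have equal length")
      d <- a - b
    }
    if (sd(d) == 0 && mean(d) == mu) {
      # identical paired samples: no effect, no variance; report t = 0
      return(structure(list(statistic = 0, df = length(d) - 1, p = 1,
                            p_adjusted = 1, kind = kind),
                       class = "rpmc_test"))
    }
    ht <- t.test(d, mu = mu)
  } else {
    if (length(a) < 2 || length(b) < 2)
      stop_input("independent-samples tests need n >= 2 per group")
    if (sd(a) == 0 && sd(b) == 0 && mean(a) - mean(b) == mu)
      stop_rpmc("rpmc_degenerate_error",
                "zero variance in both samples and equal means: t undefined")
    ht <- t.test(a, b, mu = mu, var.equal = (kind == "independent"))
  }
  p <- unname(ht$p.value)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = p,
                 p_adjusted = min(1, m * p),
                 kind = kind), class = "rpmc_test")
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample test against a normal distribution with mean and SD
#' estimated from the data. Because parameters are estimated, the
#' Lilliefors-corrected version is the default; the plain KS test
#' (estimated parameters plugged in, anti-conservative) is available
#' via `lilliefors = FALSE`.
#'
#' @param values numeric sample, n >= 5.
#' @param lilliefors use Lilliefors critical values (default `TRUE`).
#' @return List of class `rpmc_test` (`statistic, df, p, p_adjusted,
#'   kind = "ks"`).
#' @export
ks_normality <- function(values, lilliefors = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 5)
    stop_input("normality check requires at least 5 finite values")
  ht <- if (lilliefors) nortest::lillie.test(values)
  else suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  structure(list(statistic = unname(ht$statistic), df = length(values),
                 p = unname(ht$p.value), p_adjusted = unname(ht$p.value),
                 kind = "ks"), class = "rpmc_test")
}

#' Moderated multiple regression of behavioural change on stress markers
#'
#' Ordinary least squares fit of the 9-predictor change model: group
#' dummy (0 = control, 1 = stress), the three AUC_I markers
#' (ln cortisol, ln HR, ln RMSSD), their interactions with group
#' (product columns), and BMI and age as covariates. Returns the
#' model F-test against the intercept-only model, R^2, Durbin-Watson
#' statistic, and variance inflation factors per predictor
#' (collinearity is reported, never auto-remediated).
#'
#' @param data data frame holding the dependent variable and columns
#'   `group01, auc_lncort, auc_lnhr, auc_lnrmssd, bmi, age`; at least 12
#'   complete rows (2 residual df) so the diagnostics are defined.
#' @param dv name of the dependent-variable column
#'   (e.g. `"change_plan"`).
#' @return List of class `rpmc_regression`: `coefficients` (data frame
#'   `term, b, se, t, p`), `F, df1, df2, p, r_squared, durbin_watson`,
#'   and `vif` (named vector).
#' @export
fit_change_model <- function(data, dv = "change_plan") {
  need <- c(dv, "group01", "auc_lncort", "auc_lnhr", "auc_lnrmssd",
            "bmi", "age")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_input(paste("missing columns:", paste(miss, collapse = ", ")))
  d <- data.frame(
    y = data[[dv]],
    group = data$group01,
    auc_cortisol = data$auc_lncort,
    auc_hr = data$auc_lnhr,
    auc_rmssd = data$auc_lnrmssd,
    bmi = data$bmi,
    age = data$age)
  if (!all(d$group %in% c(0, 1)))
    stop_input("group01 must be dummy-coded 0 (control) / 1 (stress)")
  d$group_x_cortisol <- d$group * d$auc_cortisol
  d$group_x_hr <- d$group * d$auc_hr
  d$group_x_rmssd <- d$group * d$auc_rmssd
  d <- d[complete.cases(d), , drop = FALSE]
  p_n <- 9L
  if (nrow(d) <= p_n + 2)  # at least 2 residual df for the diagnostics
    stop_rpmc("rpmc_insufficient_data_error",
              sprintf("need at least %d complete rows for %d predictors, got %d",
                      p_n + 3, p_n, nrow(d)))

  X <- model.matrix(~ group + auc_cortisol + auc_hr + auc_rmssd +
                      group_x_cortisol + group_x_hr + group_x_rmssd +
                      bmi + age, data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_rpmc("rpmc_rank_error",
              paste("perfectly collinear predictor column(s):",
                    paste(dropped, collapse = ", ")))
  }

  fit <- lm(y ~ group + auc_cortisol + auc_hr + auc_rmssd +
              group_x_cortisol + group_x_hr + group_x_rmssd + bmi + age,
            data = d)
  # an exactly linear outcome leaves no residual variance; the fit is
  # legitimate (R^2 = 1) but VIF/SE inference is not defined there
  perfect <- mean(fit$residuals^2) < 1e-12 * (var(d$y) + 1e-300)
  sm <- if (perfect) suppressWarnings(summary(fit)) else summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), b = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vif <- if (perfect) setNames(rep(NA_real_, p_n), coefs$term[-1])
  else car::vif(fit)
  dw <- unname(lmtest::dwtest(fit)$statistic)

  structure(list(
    coefficients = coefs,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]),
    df2 = unname(sm$fstatistic[3]),
    p = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE)),
    r_squared = unname(sm$r.squared),
    durbin_watson = dw,
    vif = vif,
    n = nrow(d)
  ), class = "rpmc_regression")
}

#' @export
print.rpmc_regression <- function(x, ...) {
  cat(sprintf("Moderated change regression: F(%d, %d) = %.3f, p = %.4g, R^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$r_squared))
  cat(sprintf("Durbin-Watson = %.3f; max VIF = %.1f\n",
              x$durbin_watson, suppressWarnings(max(x$vif, na.rm = TRUE))))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @export
print.rpmc_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.3f, df = %.4g, p = %.4g (adjusted %.4g)\n",
              x$kind, x$statistic, if (is.null(x$df)) NA else x$df,
              x$p, x$p_adjusted))
  invisible(x)
}
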