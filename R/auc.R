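# Area-under-the-curve stress markers (Pruessner-style formulas).
#
# AUC with respect to ground (AUC_G) is the trapezoidal area under the
# marker curve over the analysis window; AUC with respect to increase
# (AUC_I) subtracts the rectangle spanned by the first measurement of
# the window: AUC_I = AUC_G - value(first) * (t_last - t_first). AUC_I
# therefore isolates the response (reactivity) from the baseline level
# and is negative for net decreases.

#' Default analysis windows per marker
#'
#' Heart rate and ln-RMSSD use the manipulation window t3-t7 (last
#' pre-manipulation interval through first post-manipulation interval);
#' ln-cortisol uses t2-t5 (stressor onset through the final sample),
#' accommodating the delayed endocrine response.
#'
#' @return Named list of `c(first_label, last_label)` pairs.
#' @export
marker_windows <- function() {
  list(HR = c("t3", "t7"),
       lnHR = c("t3", "t7"),
       lnRMSSD = c("t3", "t7"),
       lnCortisol = c("t2", "t5"))
}

# Resolve a label window to row indices of a single-marker series.
window_rows <- function(ts, window) {
  i1 <- match(window[1], ts$label)
  i2 <- match(window[2], ts$label)
  if (is.na(i1) || is.na(i2) || i2 < i1)
    stop_input(sprintf("window labels %s-%s not found in series",
                       window[1], window[2]))
  seq(i1, i2)
}

#' Area under the curve with respect to ground
#'
#' @param ts single-marker time series: data frame with `time_min`,
#'   `value` and (if `window` is used) `label` columns, times strictly
#'   increasing in minutes.
#' @param window optional `c(first_label, last_label)` pair restricting
#'   the computation; default uses all points.
#' @return Trapezoidal area in marker-units x minutes.
#' @examples
#' auc_ground(data.frame(time_min = c(0, 10), value = c(2, 4)))  # 30
#' @export
auc_ground <- function(ts, window = NULL) {
  rows <- if (is.null(window)) seq_len(nrow(ts)) else window_rows(ts, window)
  t <- ts$time_min[rows]
  v <- ts$value[rows]
  ok <- is.finite(v)
  t <- t[ok]; v <- v[ok]
  if (length(t) < 2)
    stop_input("AUC requires at least 2 finite points inside the window")
  pracma::trapz(t, v)
}

#' Area under the curve with respect to increase
#'
#' `auc_i = auc_g - value(first point of window) * (t_last - t_first)`;
#' the baseline is the first measurement inside the analyzed window.
#'
#' @inheritParams auc_ground
#' @param marker,participant_id optional identifiers carried into the
#'   result.
#' @return A one-row data frame (`participant_id, marker, window,
#'   auc_g, auc_i`).
#' @export
auc_increase <- function(ts, window = NULL, marker = NA_character_,
                         participant_id = NA_character_) {
  rows <- if (is.null(window)) seq_len(nrow(ts)) else window_rows(ts, window)
  sub <- ts[rows, , drop = FALSE]
  ok <- is.finite(sub$value)
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) < 2)
    stop_input("AUC requires at least 2 finite points inside the window")
  auc_g <- pracma::trapz(sub$time_min, sub$value)
  span <- sub$time_min[nrow(sub)] - sub$time_min[1]
  auc_i <- auc_g - sub$value[1] * span
  data.frame(participant_id = participant_id, marker = marker,
             window = if (is.null(window)) sprintf("%s-%s", sub$label[1],
                                                   sub$label[nrow(sub)])
             else paste(window, collapse = "-"),
             auc_g = auc_g, auc_i = auc_i, stringsAsFactors = FALSE)
}

#' AUC_I stress markers for a whole cohort
#'
#' Applies [auc_increase()] with the default windows ([marker_windows()])
#' to every participant's marker series: ln HR and ln RMSSD over t3-t7,
#' ln cortisol over t2-t5. Heart rate is ln-transformed here (marker
#' label `lnHR`) to match the analysis scale of the other markers; set
#' `hr_log = FALSE` to integrate raw bpm.
#'
#' @param markers long marker data frame (`participant_id, marker,
#'   label, time_min, value`) as produced by the extraction stage.
#' @param windows named list of label windows, default [marker_windows()].
#' @param hr_log ln-transform HR values before integrating.
#' @return Data frame `participant_id, marker, window, auc_g, auc_i`.
#' @export
cohort_auc <- function(markers, windows = marker_windows(), hr_log = TRUE) {
  out <- list()
  for (pid in unique(markers$participant_id)) {
    for (mk in unique(markers$marker[markers$participant_id == pid])) {
      ts <- markers[markers$participant_id == pid & markers$marker == mk, ]
      label <- mk
      if (mk == "HR" && hr_log) {
        ts$value <- log(ts$value)
        label <- "lnHR"
      }
      w <- windows[[label]]
      if (is.null(w)) w <- windows[[mk]]
      if (is.null(w)) next
      out[[length(out) + 1L]] <-
        auc_increase(ts, window = w, marker = label, participant_id = pid)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
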