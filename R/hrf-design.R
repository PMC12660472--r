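#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical double-gamma HRF (response peak 6 s, undershoot peak
#' 16 s, undershoot ratio 1/6) on the acquisition grid and normalises it to
#' unit sum, so that convolving a long unit boxcar yields a plateau of 1 and
#' regressor amplitudes stay in the units of the boxcar (here, percent signal
#' change).
#'
#' @param tr_seconds sampling interval (the repetition time), seconds.
#' @param duration_seconds length of the sampled kernel, seconds.
#' @param peak,undershoot gamma shape parameters (scale fixed at 1 s).
#' @param ratio undershoot amplitude relative to the response.
#' @return numeric vector of kernel weights summing to 1.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32,
                          peak = 6, undershoot = 16, ratio = 1 / 6) {
  stopifnot(tr_seconds > 0, duration_seconds > tr_seconds)
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / sum(h)
}

#' Condition boxcar on the volume grid
#'
#' A volume belongs to an event when its acquisition start time falls in the
#' half-open interval [onset, onset + duration). Onsets are 0-based seconds
#' from run start; volume i starts at (i - 1) * TR.
#'
#' @param events data frame with columns onset, duration, trial_type.
#' @param condition condition label to extract.
#' @param n_volumes number of volumes in the run.
#' @param tr_seconds repetition time, seconds.
#' @return 0/1 numeric vector of length \code{n_volumes}.
#' @export
condition_boxcar <- function(events, condition, n_volumes, tr_seconds) {
  t0 <- (seq_len(n_volumes) - 1) * tr_seconds
  box <- numeric(n_volumes)
  ev <- events[events$trial_type == condition, , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    box[t0 >= ev$onset[k] & t0 < ev$onset[k] + ev$duration[k]] <- 1
  }
  box
}

#' HRF-convolved condition regressor
#'
#' @inheritParams condition_boxcar
#' @param hrf kernel from [canonical_hrf()]; defaults to the canonical
#'   double-gamma sampled at \code{tr_seconds}.
#' @return numeric vector of length \code{n_volumes}.
#' @export
condition_regressor <- function(events, condition, n_volumes, tr_seconds,
                                hrf = canonical_hrf(tr_seconds)) {
  box <- condition_boxcar(events, condition, n_volumes, tr_seconds)
  stats::convolve(box, rev(hrf), type = "open")[seq_len(n_volumes)]
}

#' Design matrix for a block NF run
#'
#' Builds the columns used by both the streaming engine and the offline GLM:
#' intercept, linear trend (scaled to [0, 1]), and HRF-convolved regressors
#' for the requested conditions. Rest is never a column; it is the implicit
#' baseline.
#'
#' @param design block design from [make_block_design()].
#' @param n_volumes number of volumes.
#' @param tr_seconds repetition time, seconds.
#' @param conditions conditions to convolve into columns (rest excluded).
#' @param trend include the linear-trend column.
#' @return numeric matrix with named columns.
#' @export
build_design_matrix <- function(design, n_volumes, tr_seconds,
                                conditions = "meditation", trend = TRUE) {
  conditions <- setdiff(conditions, "rest")
  hrf <- canonical_hrf(tr_seconds)
  cols <- list(intercept = rep(1, n_volumes))
  if (trend) {
    cols$trend <- seq(0, 1, length.out = n_volumes)
  }
  for (cond in conditions) {
    cols[[cond]] <- condition_regressor(design$events, cond, n_volumes,
                                        tr_seconds, hrf)
  }
  do.call(cbind, cols)
}
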