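#' Configuration of the real-time NF computation
#'
#' @param responsive_fraction fraction of target-ROI voxels used for scoring
#'   (the most meditation-responsive ones), in (0, 1].
#' @param thermometer_levels number of discrete feedback levels.
#' @param score_floor_pct percent signal change mapped to the top level
#'   (strongest rewarded deactivation).
#' @param score_ceiling_pct percent signal change mapped to the bottom level.
#' @param hemodynamic_shift_s scoring-window shift applied to block onsets to
#'   respect haemodynamic lag, seconds.
#' @param mode \code{"veridical"} (scores from the participant's own brain)
#'   or \code{"sham"} (displayed scores replayed from a yoked donor).
#' @param psc_summary block summary of the per-volume percent signal change:
#'   \code{"mean"} or \code{"peak"} (the most negative volume).
#' @return an object of class \code{nf_config}.
#' @export
nf_config <- function(responsive_fraction = 0.33, thermometer_levels = 20,
                      score_floor_pct = -1.0, score_ceiling_pct = 0.0,
                      hemodynamic_shift_s = 4.0,
                      mode = c("veridical", "sham"),
                      psc_summary = c("mean", "peak")) {
  mode <- match.arg(mode)
  psc_summary <- match.arg(psc_summary)
  stopifnot(responsive_fraction > 0, responsive_fraction <= 1,
            thermometer_levels >= 2, score_floor_pct < score_ceiling_pct,
            hemodynamic_shift_s >= 0)
  structure(list(responsive_fraction = responsive_fraction,
                 thermometer_levels = as.integer(thermometer_levels),
                 score_floor_pct = score_floor_pct,
                 score_ceiling_pct = score_ceiling_pct,
                 hemodynamic_shift_s = hemodynamic_shift_s,
                 mode = mode, psc_summary = psc_summary),
            class = "nf_config")
}

#' Initialise an incremental GLM state
#'
#' The state carries the sufficient statistics of cumulative ordinary least
#' squares (X'X, X'Y, per-voxel sums of squares) plus the streamed data, so
#' that coefficients at volume t always equal a full refit on volumes 1..t.
#'
#' @param n_voxels number of voxels streamed per volume.
#' @param design_columns column names of the design rows that will be fed in
#'   (e.g. intercept, trend, meditation).
#' @return an object of class \code{nf_glm_state}.
#' @export
incremental_glm_init <- function(n_voxels, design_columns) {
  p <- length(design_columns)
  structure(list(XtX = matrix(0, p, p), XtY = matrix(0, p, n_voxels),
                 yty = numeric(n_voxels), volumes_seen = 0L,
                 design_columns = design_columns,
                 n_voxels = as.integer(n_voxels),
                 Y = NULL, X = NULL),
            class = "nf_glm_state")
}

#' Stream one volume into the incremental GLM
#'
#' Volumes containing non-finite intensities are rejected with a warning and
#' the state is returned unchanged.
#'
#' @param state an [incremental_glm_init()] state.
#' @param new_volume per-voxel intensities at this volume.
#' @param design_row regressor values at this volume, in the order of
#'   \code{state$design_columns}.
#' @return the updated state.
#' @export
update_incremental_glm <- function(state, new_volume, design_row) {
  stopifnot(inherits(state, "nf_glm_state"),
            length(design_row) == length(state$design_columns),
            length(new_volume) == state$n_voxels)
  if (any(!is.finite(new_volume))) {
    warning("volume rejected: non-finite intensities")
    return(state)
  }
  x <- as.numeric(design_row)
  y <- as.numeric(new_volume)
  state$XtX <- state$XtX + tcrossprod(x)
  state$XtY <- state$XtY + x %o% y
  state$yty <- state$yty + y^2
  state$volumes_seen <- state$volumes_seen + 1L
  state$Y <- rbind(state$Y, y)
  state$X <- rbind(state$X, x)
  state
}

#' Cumulative GLM state from in-memory data
#'
#' Equivalent to streaming volumes \code{1..upto} through
#' [update_incremental_glm()] one at a time (the equivalence is a tested
#' invariant); used where the full run is already in memory and scores are
#' only needed at block boundaries.
#'
#' @param Y volumes-by-voxels data matrix.
#' @param X volumes-by-columns design matrix with column names.
#' @param upto last volume to include.
#' @return an \code{nf_glm_state}.
#' @export
glm_state_from_data <- function(Y, X, upto = nrow(Y)) {
  stopifnot(nrow(Y) == nrow(X), upto >= 1, upto <= nrow(Y))
  Ys <- Y[seq_len(upto), , drop = FALSE]
  Xs <- X[seq_len(upto), , drop = FALSE]
  structure(list(XtX = crossprod(Xs), XtY = crossprod(Xs, Ys),
                 yty = colSums(Ys^2), volumes_seen = as.integer(upto),
                 design_columns = colnames(X),
                 n_voxels = ncol(Y), Y = Ys, X = Xs),
            class = "nf_glm_state")
}

glm_is_fitted <- function(state) {
  p <- length(state$design_columns)
  state$volumes_seen >= p + 1 &&
    rcond(state$XtX) > .Machine$double.eps * 100
}

#' Coefficients and meditation-vs-rest t-statistics of the streamed GLM
#'
#' @param state a fitted [nf_glm_state] (at least p + 1 volumes streamed).
#' @return list with \code{beta} (columns = voxels), \code{t} (t-statistic of
#'   the meditation column per voxel, NA if that column is absent),
#'   \code{sigma2} and \code{df}.
#' @export
incremental_glm_coef <- function(state) {
  if (!glm_is_fitted(state)) {
    stop("incremental GLM is underdetermined: ",
         state$volumes_seen, " volume(s) for ",
         length(state$design_columns), " columns")
  }
  p <- length(state$design_columns)
  XtXinv <- solve(state$XtX)
  beta <- XtXinv %*% state$XtY
  rownames(beta) <- state$design_columns
  rss <- state$yty - colSums(beta * state$XtY)
  df <- state$volumes_seen - p
  sigma2 <- pmax(rss, 0) / df
  t_med <- rep(NA_real_, state$n_voxels)
  if ("meditation" %in% state$design_columns) {
    j <- match("meditation", state$design_columns)
    se <- sqrt(sigma2 * XtXinv[j, j])
    t_med <- ifelse(se > 0, beta[j, ] / se, NA_real_)
  }
  list(beta = beta, t = t_med, sigma2 = sigma2, df = df)
}

#' Select the voxels most responsive to meditation
#'
#' Deactivation is the target, so responsiveness means the most negative
#' meditation-vs-rest t-statistic. Returns \code{max(1,
#' floor(responsive_fraction * V))} voxel ids; ties break by ascending id.
#'
#' @param state a fitted [nf_glm_state].
#' @param config an [nf_config()].
#' @param direction \code{"negative"} (default; most negative t first) or
#'   \code{"absolute"} (largest |t| first, used for the confound ROI).
#' @return integer vector of selected voxel ids.
#' @export
select_responsive_voxels <- function(state, config,
                                     direction = c("negative", "absolute")) {
  direction <- match.arg(direction)
  fit <- incremental_glm_coef(state)
  if (all(is.na(fit$t))) stop("state has no meditation t-statistics")
  k <- max(1L, floor(config$responsive_fraction * state$n_voxels))
  key <- if (direction == "negative") fit$t else -abs(fit$t)
  ord <- order(key, seq_along(key))
  sort(ord[seq_len(k)])
}

#' Per-volume percent signal change against the cumulative rest baseline
#'
#' The baseline is the detrended prediction of the cumulative GLM with the
#' meditation effect removed (intercept + trend at each volume), i.e. the
#' model's estimate of the average rest signal up to now.
#'
#' @param state a fitted [nf_glm_state].
#' @param voxels voxel ids to average over.
#' @return numeric vector: mean PSC across the given voxels at every streamed
#'   volume.
#' @export
psc_series <- function(state, voxels) {
  fit <- incremental_glm_coef(state)
  base_cols <- intersect(c("intercept", "trend"), state$design_columns)
  j <- match(base_cols, state$design_columns)
  baseline <- state$X[, j, drop = FALSE] %*% fit$beta[j, voxels, drop = FALSE]
  if (any(baseline <= 0)) {
    stop("degenerate intensities: cumulative baseline estimate <= 0")
  }
  obs <- state$Y[, voxels, drop = FALSE]
  rowMeans(100 * (obs - baseline) / baseline)
}

block_volume_window <- function(onset, duration, shift_s, tr, n_avail) {
  t0 <- (seq_len(n_avail) - 1) * tr
  which(t0 >= onset + shift_s & t0 < onset + duration + shift_s)
}

#' Raw NF score of one meditation block
#'
#' Averages the per-volume PSC of the selected voxels over the block's
#' volumes, after shifting the window by the haemodynamic lag. Intermittency
#' contract: the block's shifted window must have fully elapsed.
#'
#' @param state a fitted [nf_glm_state] streamed at least to the end of the
#'   shifted block window.
#' @param selected_voxels voxel ids (from [select_responsive_voxels()]).
#' @param block one row of the events table (a meditation event).
#' @param shift_s haemodynamic shift, seconds.
#' @param tr_seconds repetition time, seconds.
#' @param summary \code{"mean"} or \code{"peak"} (most negative volume).
#' @return the block PSC (percent).
#' @export
compute_block_psc <- function(state, selected_voxels, block, shift_s,
                              tr_seconds, summary = "mean") {
  last_needed <- ceiling((block$onset + block$duration + shift_s) /
                           tr_seconds)
  if (state$volumes_seen < last_needed) {
    stop("block not fully elapsed: scores are intermittent, computed only ",
         "after the shifted block window")
  }
  psc <- psc_series(state, selected_voxels)
  win <- block_volume_window(block$onset, block$duration, shift_s,
                             tr_seconds, state$volumes_seen)
  if (length(win) == 0) stop("empty block window")
  if (identical(summary, "peak")) min(psc[win]) else mean(psc[win])
}

#' Residualize the target PSC series against the confound ROI
#'
#' Cumulative least squares of target on (intercept + confound); returns the
#' residual series. A constant confound series degrades to an intercept-only
#' fit with a warning.
#'
#' @param raw_psc_series per-volume target PSC.
#' @param confound_psc_series per-volume confound PSC, same length.
#' @return numeric residual series.
#' @export
residualize_against_confound <- function(raw_psc_series,
                                         confound_psc_series) {
  stopifnot(length(raw_psc_series) == length(confound_psc_series))
  if (stats::sd(confound_psc_series) < .Machine$double.eps * 100) {
    warning("constant confound series: intercept-only fit")
    return(raw_psc_series - mean(raw_psc_series))
  }
  stats::lm.fit(cbind(1, confound_psc_series), raw_psc_series)$residuals
}

#' Map a residualized block score to a thermometer level
#'
#' Linear map of PSC from [ceiling, floor] onto levels [1, L], clipped at
#' both ends and rounded half away from zero. More negative PSC (stronger
#' deactivation) gives a higher level.
#'
#' @param residual_psc block score, percent signal change.
#' @param config an [nf_config()].
#' @return integer level in [1, thermometer_levels].
#' @export
map_to_thermometer <- function(residual_psc, config) {
  L <- config$thermometer_levels
  span <- config$score_ceiling_pct - config$score_floor_pct
  x <- 1 + (L - 1) * (config$score_ceiling_pct - residual_psc) / span
  x <- pmin(pmax(x, 1), L)
  as.integer(sign(x) * floor(abs(x) + 0.5))   # round half away from zero
}

#' Yoked-sham schedule
#'
#' @param donor_id donor subject id.
#' @param donor_scores data frame of the donor's per-block scores (one row
#'   per block in presentation order, with columns run, block,
#'   residual_psc, level).
#' @param matching_key donor meditation-experience hours used for yoking.
#' @return an object of class \code{nf_sham_schedule}.
#' @export
sham_schedule <- function(donor_id, donor_scores, matching_key = NA_real_) {
  stopifnot(all(c("run", "block", "residual_psc", "level") %in%
                  names(donor_scores)))
  structure(list(donor_id = donor_id, donor_scores = donor_scores,
                 matching_key = matching_key),
            class = "nf_sham_schedule")
}

#' Match a sham recipient to the nearest-experience donor
#'
#' @param donor_hours named numeric vector of donors' meditation-experience
#'   hours (names are donor ids).
#' @param recipient_hours the recipient's hours.
#' @return the matched donor id (nearest hours; ties by ascending donor id).
#' @export
match_sham_donor <- function(donor_hours, recipient_hours) {
  d <- abs(donor_hours - recipient_hours)
  ids <- names(donor_hours)
  ids[order(d, ids)][1]
}

#' Blinding check: are displayed sham scores contingent on the recipient?
#'
#' The block-design task imposes a deterministic within-session score
#' profile that is common to every subject, so raw block-level correlations
#' between independent donor and recipient scores are inflated. Given an
#' ensemble of independent sham pairs, each block cell is centred across
#' pairs (removing the design-driven profile) and the displayed-vs-actual
#' correlation is tested per pair; under non-contingent (yoked) feedback
#' these p-values are approximately uniform.
#'
#' @param displayed blocks-by-pairs matrix of displayed (donor) scores.
#' @param actual blocks-by-pairs matrix of the recipients' actual scores.
#' @return data frame with one row per pair: r, p, n_blocks.
#' @export
sham_blinding_pvalues <- function(displayed, actual) {
  stopifnot(identical(dim(displayed), dim(actual)), ncol(displayed) >= 3)
  Dc <- displayed - rowMeans(displayed)
  Ac <- actual - rowMeans(actual)
  n <- nrow(Dc)
  out <- lapply(seq_len(ncol(Dc)), function(j) {
    r <- stats::cor(Dc[, j], Ac[, j])
    data.frame(pair = j, r = r, p = correlation_p(r, n - 2),
               n_blocks = n)
  })
  do.call(rbind, out)
}

#' Run one intermittent NF session
#'
#' Streams each run volume-by-volume through the incremental GLM; after each
#' meditation block's shifted window has elapsed it (i) re-selects the most
#' responsive target voxels, (ii) computes the block PSC of target and
#' confound ROIs against their cumulative rest baselines, (iii) residualizes
#' the target PSC series against the confound PSC series by cumulative least
#' squares, and (iv) maps the block's residual score onto the thermometer.
#' In sham mode the displayed level and score are the donor's, replayed in
#' order, while the recipient's actual scores are still computed and logged
#' for the blinding check.
#'
#' @param runs list of [simulate_roi_run()] objects (one per NF run).
#' @param config an [nf_config()].
#' @param sham an [sham_schedule()]; required when \code{config$mode} is
#'   \code{"sham"}.
#' @return data frame of class \code{nf_session_log} with one row per
#'   meditation block: run, block, raw_psc, residual_psc, level,
#'   displayed_psc, displayed_level, n_selected.
#' @export
run_nf_session <- function(runs, config = nf_config(), sham = NULL) {
  if (config$mode == "sham") {
    if (is.null(sham)) stop("sham mode needs a sham_schedule")
    n_blocks <- sum(vapply(runs, function(r)
      sum(r$design$events$trial_type == "meditation"), integer(1)))
    if (nrow(sham$donor_scores) != n_blocks) {
      stop(sprintf("replay error: donor has %d scores, session needs %d",
                   nrow(sham$donor_scores), n_blocks))
    }
  }
  logs <- list()
  blk_i <- 0L
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    tr <- run$acquisition$tr_seconds
    nv <- ncol(run$target)
    cols <- c("intercept", "trend", "meditation")
    Xfull <- build_design_matrix(run$design, nv, tr)
    colnames(Xfull) <- cols
    Yt <- t(run$target)
    Yc <- t(run$confound)
    med_ev <- run$design$events[run$design$events$trial_type == "meditation",
                                , drop = FALSE]
    # volume index after which each block's shifted window has elapsed
    due <- vapply(seq_len(nrow(med_ev)), function(k)
      ceiling((med_ev$onset[k] + med_ev$duration[k] +
                 config$hemodynamic_shift_s) / tr), numeric(1))
    due <- pmin(due, nv)
    for (next_block in seq_len(nrow(med_ev))) {
      v <- due[next_block]
      st_t <- glm_state_from_data(Yt, Xfull, v)
      st_c <- glm_state_from_data(Yc, Xfull, v)
      {
        blk <- med_ev[next_block, ]
        sel <- select_responsive_voxels(st_t, config)
        sel_c <- select_responsive_voxels(st_c, config,
                                          direction = "absolute")
        tgt_psc <- psc_series(st_t, sel)
        cfd_psc <- psc_series(st_c, sel_c)
        resid <- residualize_against_confound(tgt_psc, cfd_psc)
        win <- block_volume_window(blk$onset, blk$duration,
                                   config$hemodynamic_shift_s, tr,
                                   st_t$volumes_seen)
        raw <- compute_block_psc(st_t, sel, blk,
                                 config$hemodynamic_shift_s, tr,
                                 config$psc_summary)
        res_score <- if (identical(config$psc_summary, "peak"))
          min(resid[win]) else mean(resid[win])
        level <- map_to_thermometer(res_score, config)
        blk_i <- blk_i + 1L
        if (config$mode == "sham") {
          disp_psc <- sham$donor_scores$residual_psc[blk_i]
          disp_level <- sham$donor_scores$level[blk_i]
        } else {
          disp_psc <- res_score
          disp_level <- level
        }
        logs[[blk_i]] <- data.frame(run = ri, block = next_block,
                                    raw_psc = raw, residual_psc = res_score,
                                    level = level, displayed_psc = disp_psc,
                                    displayed_level = disp_level,
                                    n_selected = length(sel))
      }
    }
  }
  out <- do.call(rbind, logs)
  class(out) <- c("nf_session_log", "data.frame")
  out
}
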