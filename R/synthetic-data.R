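#' Acquisition parameters for an NF run
#'
#' The defaults mirror a 7-T protocol with TR = 0.8 s and 10-minute NF runs,
#' three runs per session and two sessions.
#'
#' @param tr_seconds repetition time, seconds.
#' @param run_length_seconds run duration, seconds; the number of volumes is
#'   \code{floor(run_length_seconds / tr_seconds)}.
#' @param n_runs_per_session,n_sessions session bookkeeping.
#' @return an object of class \code{nf_acquisition}.
#' @export
nf_acquisition <- function(tr_seconds = 0.8, run_length_seconds = 600,
                           n_runs_per_session = 3, n_sessions = 2) {
  stopifnot(tr_seconds > 0, run_length_seconds > 0,
            n_runs_per_session >= 1, n_sessions >= 1)
  structure(list(tr_seconds = tr_seconds,
                 run_length_seconds = run_length_seconds,
                 n_volumes = floor(run_length_seconds / tr_seconds),
                 n_runs_per_session = as.integer(n_runs_per_session),
                 n_sessions = as.integer(n_sessions)),
            class = "nf_acquisition")
}

#' Ground-truth parameters for the ROI simulator
#'
#' @param target_deactivation_pct meditation-vs-rest amplitude in percent
#'   signal change; negative values are deactivation.
#' @param coupling_gamma PPI modulation coefficient used by the coupled-grid
#'   generator.
#' @param drift_amplitude peak-to-peak low-frequency drift, percent.
#' @param physio_sd standard deviation of the shared physiological nuisance
#'   component, percent.
#' @param thermal_sd standard deviation of white (thermal) noise, percent.
#' @param signal_fraction fraction of target voxels carrying the effect.
#' @param seed RNG seed.
#' @return an object of class \code{nf_ground_truth}.
#' @export
nf_ground_truth <- function(target_deactivation_pct = -0.5,
                            coupling_gamma = 0, drift_amplitude = 0.3,
                            physio_sd = 0.2, thermal_sd = 0.5,
                            signal_fraction = 0.5, seed = 1L) {
  vals <- c(target_deactivation_pct, coupling_gamma, drift_amplitude,
            physio_sd, thermal_sd, signal_fraction)
  if (any(!is.finite(vals))) {
    stop("ground-truth parameters must be finite")
  }
  stopifnot(thermal_sd >= 0, physio_sd >= 0,
            signal_fraction > 0, signal_fraction <= 1)
  structure(list(target_deactivation_pct = target_deactivation_pct,
                 coupling_gamma = coupling_gamma,
                 drift_amplitude = drift_amplitude,
                 physio_sd = physio_sd, thermal_sd = thermal_sd,
                 signal_fraction = signal_fraction, seed = as.integer(seed)),
            class = "nf_ground_truth")
}

#' Block design of one NF run
#'
#' Lays out the mandated structure rest - (cue, meditation, feedback) x 3 -
#' rest - (cue, meditation, feedback) x 3 - rest: three rest blocks of 51 s
#' and six meditation blocks of 26 s, each meditation block preceded by a cue
#' and followed by an intermittent feedback display. Time left over at the
#' end of the run is an unmodeled gap.
#'
#' @param acquisition an [nf_acquisition()].
#' @param cue_s,feedback_s cue and feedback durations, seconds.
#' @param rest_s,meditation_s block durations, seconds.
#' @return an object of class \code{nf_block_design} with an \code{events}
#'   data frame (onset, duration, trial_type; seconds, 0-based onsets).
#' @export
make_block_design <- function(acquisition = nf_acquisition(),
                              cue_s = 3, feedback_s = 10,
                              rest_s = 51, meditation_s = 26) {
  stopifnot(cue_s >= 0, feedback_s >= 0, rest_s > 0, meditation_s > 0)
  total <- 3 * rest_s + 6 * (cue_s + meditation_s + feedback_s)
  if (total > acquisition$run_length_seconds) {
    stop(sprintf(
      "run too short for the mandated blocks: need %.1f s, have %.1f s (deficit %.1f s)",
      total, acquisition$run_length_seconds,
      total - acquisition$run_length_seconds))
  }
  onset <- 0
  rows <- list()
  add <- function(type, dur) {
    rows[[length(rows) + 1]] <<- data.frame(onset = onset, duration = dur,
                                            trial_type = type)
    onset <<- onset + dur
  }
  for (half in 1:2) {
    add("rest", rest_s)
    for (pair in 1:3) {
      if (cue_s > 0) add("cue", cue_s)
      add("meditation", meditation_s)
      if (feedback_s > 0) add("feedback", feedback_s)
    }
  }
  add("rest", rest_s)
  events <- do.call(rbind, rows)
  structure(list(events = events, rest_duration = rest_s,
                 meditation_duration = meditation_s,
                 n_rest = 3L, n_meditation = 6L),
            class = "nf_block_design")
}

#' Simulate ROI-collapsed BOLD time series for one NF run
#'
#' Each target voxel follows
#' \code{baseline * (1 + (signal + drift + physio + thermal) / 100)}:
#' the signal is the HRF-convolved meditation boxcar scaled by the configured
#' percent-signal-change amplitude (carried by a random subset of voxels,
#' with mean-preserving amplitude heterogeneity), the drift is a slow
#' linear-plus-half-cosine trend, and the physiological component is a
#' smoothed noise series shared between target and confound ROIs with
#' voxel-specific loadings. Confound voxels carry the shared physiological
#' component plus independent thermal noise, but no meditation signal.
#'
#' @param design an [make_block_design()] result.
#' @param acquisition an [nf_acquisition()].
#' @param truth an [nf_ground_truth()].
#' @param n_target_voxels,n_confound_voxels ROI sizes (each >= 3).
#' @param seed RNG seed; defaults to the seed in \code{truth}.
#' @return an object of class \code{nf_roi_run}: target and confound
#'   voxels-by-volumes matrices, the design, acquisition, per-voxel
#'   baselines, and the ids of signal-carrying target voxels.
#' @export
simulate_roi_run <- function(design, acquisition, truth,
                             n_target_voxels = 50, n_confound_voxels = 30,
                             seed = truth$seed) {
  stopifnot(inherits(design, "nf_block_design"),
            inherits(truth, "nf_ground_truth"),
            n_target_voxels >= 3, n_confound_voxels >= 3)
  set.seed(seed)
  nv <- acquisition$n_volumes
  tr <- acquisition$tr_seconds

  med <- condition_regressor(design$events, "meditation", nv, tr)
  tfrac <- seq(0, 1, length.out = nv)
  drift <- truth$drift_amplitude * (tfrac - 0.5) +
    0.5 * truth$drift_amplitude * cos(2 * pi * tfrac * 1.5)

  # shared low-frequency physiological nuisance: smoothed white noise,
  # rescaled to the configured sd
  physio <- if (truth$physio_sd > 0) {
    raw <- stats::filter(stats::rnorm(nv + 40), rep(1, 8), sides = 1)
    raw <- raw[!is.na(raw)][seq_len(nv)]
    truth$physio_sd * (raw - mean(raw)) / stats::sd(raw)
  } else {
    numeric(nv)
  }

  n_signal <- max(1L, round(truth$signal_fraction * n_target_voxels))
  signal_voxels <- sort(sample.int(n_target_voxels, n_signal))
  amp <- numeric(n_target_voxels)
  # mean-preserving heterogeneity across signal carriers
  amp[signal_voxels] <- truth$target_deactivation_pct *
    stats::runif(n_signal, 0.8, 1.2)

  baseline_t <- stats::runif(n_target_voxels, 800, 1200)
  load_t <- stats::runif(n_target_voxels, 0.5, 1.5)
  pct_t <- outer(amp, med) +
    matrix(drift, n_target_voxels, nv, byrow = TRUE) +
    load_t %o% physio +
    matrix(stats::rnorm(n_target_voxels * nv, sd = truth$thermal_sd),
           n_target_voxels, nv)
  target <- baseline_t * (1 + pct_t / 100)

  baseline_c <- stats::runif(n_confound_voxels, 800, 1200)
  load_c <- stats::runif(n_confound_voxels, 0.5, 1.5)
  pct_c <- load_c %o% physio +
    matrix(stats::rnorm(n_confound_voxels * nv, sd = truth$thermal_sd),
           n_confound_voxels, nv)
  confound <- baseline_c * (1 + pct_c / 100)

  structure(list(target = target, confound = confound, design = design,
                 acquisition = acquisition, truth = truth,
                 baseline_target = baseline_t, baseline_confound = baseline_c,
                 signal_voxels = signal_voxels),
            class = "nf_roi_run")
}

#' Cohort configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 19
#' analysable participants per group, six 5-minute meditation sessions over a
#' week (days 0, 3, 4, 5, 6, 7), mindful-awareness (SMS-Mind) slopes rising
#' in the experimental group and falling in the control group, distress
#' (DASS-21 total) difference scores of -4.8 (SD 5.0) vs -1.6 (SD 3.6), a
#' decline in breath-counting accuracy in the experimental group, and a 0.71
#' correlation between coupling change and distress change in the
#' experimental group only.
#'
#' @param n_per_group participants per group.
#' @param session_days strictly increasing days of the six meditation
#'   sessions (day 0 = baseline).
#' @param sms_slope_mean_by_group named mean SMS-Mind residual slopes,
#'   points/day.
#' @param sms_body_slope_mean_by_group same for SMS-Body (null by default).
#' @param dass_change_mean_by_group,dass_change_sd_by_group DASS-21 total
#'   difference-score moments (follow-up minus baseline).
#' @param bct_change_d standardised group mean changes in BCT task accuracy
#'   (negative = decline), applied on a 10-point percent SD.
#' @param coupling_distress_r correlation between gPPI coupling beta and DASS
#'   change within each group.
#' @param sms_noise_sd residual SD of post-session SMS scores, points.
#' @param sms_slope_sd between-subject SD of the individual slopes,
#'   points/day.
#' @param sms_subject_sd between-subject SD of the stable offset in post
#'   scores, points.
#' @param seed RNG seed.
#' @return an object of class \code{nf_cohort_config}.
#' @export
cohort_config <- function(n_per_group = 19,
                          session_days = c(0, 3, 4, 5, 6, 7),
                          sms_slope_mean_by_group =
                            c(experimental = 0.05, control = -0.05),
                          sms_body_slope_mean_by_group =
                            c(experimental = 0, control = 0),
                          dass_change_mean_by_group =
                            c(experimental = -4.8, control = -1.6),
                          dass_change_sd_by_group =
                            c(experimental = 5.0, control = 3.6),
                          bct_change_d = c(experimental = -0.4, control = 0),
                          coupling_distress_r =
                            c(experimental = 0.71, control = 0),
                          sms_noise_sd = 3,
                          sms_slope_sd = 0.15,
                          sms_subject_sd = 2,
                          seed = 1L) {
  stopifnot(n_per_group >= 3, length(session_days) == 6,
            all(diff(session_days) > 0),
            all(abs(coupling_distress_r) < 1))
  if (any(dass_change_sd_by_group <= 0) || sms_noise_sd < 0 ||
      sms_slope_sd < 0 || sms_subject_sd < 0) {
    stop("standard deviations must be positive")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 session_days = session_days,
                 sms_slope_mean_by_group = sms_slope_mean_by_group,
                 sms_body_slope_mean_by_group = sms_body_slope_mean_by_group,
                 dass_change_mean_by_group = dass_change_mean_by_group,
                 dass_change_sd_by_group = dass_change_sd_by_group,
                 bct_change_d = bct_change_d,
                 coupling_distress_r = coupling_distress_r,
                 sms_noise_sd = sms_noise_sd,
                 sms_slope_sd = sms_slope_sd,
                 sms_subject_sd = sms_subject_sd,
                 seed = as.integer(seed)),
            class = "nf_cohort_config")
}

# instrument bounds: SMS-Mind 15 items, SMS-Body 6 items, both rated 1-5
.sms_bounds <- list(mind = c(15, 75), body = c(6, 30))

clip_scale <- function(x, bounds) {
  n_clipped <- sum(x < bounds[1] | x > bounds[2])
  if (n_clipped > 0) {
    message(sprintf("clipped %d value(s) to the instrument range [%g, %g]",
                    n_clipped, bounds[1], bounds[2]))
  }
  pmin(pmax(x, bounds[1]), bounds[2])
}

#' Simulate a behavioural cohort
#'
#' Generates one row per subject in wide format. Post-meditation SMS scores
#' follow subject-specific linear trajectories over the session days with
#' group-specific mean slopes, plus effects of the pre-session score,
#' sleepiness (SSS), age and sex, so that the residualization step has known
#' coefficients to recover. DASS-21 change scores are drawn with the
#' configured group means and SDs; the gPPI coupling beta is drawn jointly
#' with the DASS change at the configured within-group correlation. BCT
#' probe counts are discrete (0-5 correct probes, reported in percent).
#'
#' @param config an [cohort_config()].
#' @param covariate_effects list of pooled regression coefficients for
#'   post-SMS on pre-SMS, SSS, age and sex (used by both subscales).
#' @return data frame of class \code{nf_cohort}, one row per subject; SMS and
#'   SSS timepoint columns are suffixed \code{_t1 .. _t6}. Attribute
#'   \code{session_days} carries the schedule.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            covariate_effects = list(pre = 0.4, sss = -1.0,
                                                     age = 0.05, sex = 0.5)) {
  stopifnot(inherits(config, "nf_cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  N <- 2L * n
  group <- rep(c("experimental", "control"), each = n)
  days <- config$session_days
  ce <- covariate_effects

  age <- stats::runif(N, 19, 50)
  sex <- rep_len(c(1L, 0L), N)               # balanced binary covariate
  sss <- matrix(pmin(pmax(round(stats::rnorm(N * 6, 3, 1)), 1), 7), N, 6)
  pre_mind <- matrix(clip_scale(stats::rnorm(N * 6, 45, 6),
                                .sms_bounds$mind), N, 6)
  pre_body <- matrix(clip_scale(stats::rnorm(N * 6, 18, 3),
                                .sms_bounds$body), N, 6)

  slope_mind <- stats::rnorm(N, config$sms_slope_mean_by_group[group],
                             config$sms_slope_sd)
  slope_body <- stats::rnorm(N, config$sms_body_slope_mean_by_group[group],
                             config$sms_slope_sd)
  subj_off <- stats::rnorm(N, 0, config$sms_subject_sd)
  # subscale intercepts put the expected post score near mid-scale
  # (SMS-Mind 15 items, SMS-Body 6 items)
  traj <- function(pre, slope, intercept) {
    intercept + ce$sss * sss + ce$age * age + ce$sex * sex + subj_off +
      outer(slope, days) + ce$pre * pre +
      matrix(stats::rnorm(N * 6, 0, config$sms_noise_sd), N, 6)
  }
  post_mind <- clip_scale(traj(pre_mind, slope_mind, 30), .sms_bounds$mind)
  post_body <- clip_scale(traj(pre_body, slope_body, 12), .sms_bounds$body)

  # coupling beta and DASS change: bivariate normal at the configured r
  r <- config$coupling_distress_r[group]
  z1 <- stats::rnorm(N)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(N)
  dass_change <- config$dass_change_mean_by_group[group] +
    config$dass_change_sd_by_group[group] * z1
  coupling_beta <- ifelse(group == "experimental", -0.2, 0) + 0.15 * z2
  dass_baseline <- pmax(0, stats::rnorm(N, 20, 8))

  d_bct <- config$bct_change_d[group]
  bct_task_base <- pmin(100, pmax(0, stats::rnorm(N, 75, 12)))
  bct_task_fu <- pmin(100, pmax(0, bct_task_base + 10 * d_bct +
                                  stats::rnorm(N, 0, 10)))
  p_fu <- pmin(0.99, pmax(0.01, 0.85 + 0.1 * d_bct))
  bct_probe_base <- 20 * stats::rbinom(N, 5, 0.85)
  bct_probe_fu <- 20 * stats::rbinom(N, 5, p_fu)

  out <- data.frame(
    subject_id = sprintf("sub-%s%03d", substr(group, 1, 3),
                         c(seq_len(n), seq_len(n))),
    group = group, age = age, sex = sex,
    dass_baseline = dass_baseline,
    dass_followup = dass_baseline + dass_change,
    bct_task_baseline = bct_task_base, bct_task_followup = bct_task_fu,
    bct_probe_baseline = bct_probe_base, bct_probe_followup = bct_probe_fu,
    coupling_beta = coupling_beta,
    mfd = stats::rlnorm(N, log(0.15), 0.3),
    true_slope_mind = slope_mind, true_slope_body = slope_body)
  for (t in 1:6) {
    out[[paste0("sms_mind_pre_t", t)]] <- pre_mind[, t]
    out[[paste0("sms_mind_post_t", t)]] <- post_mind[, t]
    out[[paste0("sms_body_pre_t", t)]] <- pre_body[, t]
    out[[paste0("sms_body_post_t", t)]] <- post_body[, t]
    out[[paste0("sss_t", t)]] <- sss[, t]
  }
  attr(out, "session_days") <- days
  class(out) <- c("nf_cohort", "data.frame")
  out
}

#' Simulate a voxel grid with injected seed coupling
#'
#' Generates a seed time series and a grid of voxel series in which a chosen
#' subset of voxels carries a psychophysiological interaction: voxel = main
#' condition effect + coupling with the seed + gamma * (seed x centred
#' meditation regressor) + noise. Used for gPPI recovery and permutation
#' power checks.
#'
#' @param design,acquisition run layout.
#' @param gamma PPI modulation coefficient of the carrier voxels.
#' @param carrier_voxels integer ids of voxels carrying the modulation.
#' @param n_voxels total voxels.
#' @param noise_sd residual noise SD.
#' @param seed RNG seed.
#' @return list with \code{grid} (voxels x volumes), \code{seed_series},
#'   \code{carrier_voxels} and \code{gamma}.
#' @export
simulate_coupled_grid <- function(design, acquisition, gamma = 0.4,
                                  carrier_voxels = 1:10, n_voxels = 100,
                                  noise_sd = 1, seed = 1L) {
  set.seed(seed)
  nv <- acquisition$n_volumes
  tr <- acquisition$tr_seconds
  med <- condition_regressor(design$events, "meditation", nv, tr)
  med_c <- med - mean(med)
  seed_series <- 0.8 * med + as.numeric(
    stats::arima.sim(list(ar = 0.3), nv, sd = 1))
  ppi <- seed_series * med_c
  grid <- matrix(stats::rnorm(n_voxels * nv, sd = noise_sd), n_voxels, nv)
  grid <- grid + matrix(0.3 * med, n_voxels, nv, byrow = TRUE)
  grid[carrier_voxels, ] <- grid[carrier_voxels, , drop = FALSE] +
    matrix(gamma * ppi, length(carrier_voxels), nv, byrow = TRUE)
  list(grid = grid, seed_series = seed_series,
       carrier_voxels = carrier_voxels, gamma = gamma)
}
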