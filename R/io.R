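#' @useDynLib nfmed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# atomic write: write to a temp file in the same directory, then rename
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a BIDS-style events table
#'
#' Columns onset, duration, trial_type; onsets are 0-based seconds from run
#' start.
#'
#' @param events events data frame (e.g. \code{design$events}).
#' @param path output TSV path.
#' @export
write_events_tsv <- function(events, path) {
  atomic_write(path, function(p)
    utils::write.table(events[, c("onset", "duration", "trial_type")], p,
                       sep = "\t", row.names = FALSE, quote = FALSE))
}

#' Read and validate a BIDS-style events table
#'
#' @param path TSV path with columns onset, duration, trial_type.
#' @return validated events data frame, sorted by onset.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("onset", "duration", "trial_type"), names(ev))
  if (length(missing) > 0) {
    stop("events file missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.unsorted(ev$onset)) stop("events not sorted: non-monotone onsets")
  ends <- ev$onset + ev$duration
  if (any(ev$onset[-1] < ends[-length(ends)] - 1e-9)) {
    stop("overlapping events in column onset/duration")
  }
  ev
}

roi_to_4d <- function(mat) {
  # voxels laid out along x; a 1-voxel-thick 4D volume
  aperm(array(mat, dim = c(nrow(mat), ncol(mat), 1, 1)), c(1, 3, 4, 2))
}

#' Write an ROI run as NIfTI images plus an events TSV
#'
#' Target and confound matrices are written as 4D NIfTI (voxels along x, one
#' volume per time point, RAS+ orientation), each with a 0/1 mask image, and
#' the block design as a BIDS-style events TSV.
#'
#' @param run an \code{nf_roi_run}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named list of written paths.
#' @export
write_roi_run <- function(run, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- run$acquisition$tr_seconds
  paths <- list(
    target = file.path(dir, paste0(prefix, "_target.nii.gz")),
    target_mask = file.path(dir, paste0(prefix, "_target_mask.nii.gz")),
    confound = file.path(dir, paste0(prefix, "_confound.nii.gz")),
    confound_mask = file.path(dir, paste0(prefix, "_confound_mask.nii.gz")),
    events = file.path(dir, paste0(prefix, "_events.tsv")))
  wr <- function(mat, path) {
    img <- RNifti::asNifti(roi_to_4d(mat), pixdim = c(1, 1, 1, tr))
    RNifti::writeNifti(img, path)
  }
  wr(run$target, paths$target)
  wr(run$confound, paths$confound)
  mk_mask <- function(nvox, path) {
    RNifti::writeNifti(RNifti::asNifti(array(1L, dim = c(nvox, 1, 1))),
                       path)
  }
  mk_mask(nrow(run$target), paths$target_mask)
  mk_mask(nrow(run$confound), paths$confound_mask)
  write_events_tsv(run$design$events, paths$events)
  paths
}

#' Read an ROI run back from NIfTI + events files
#'
#' Voxels are taken where the mask is > 0; grids and masks must share their
#' spatial shape.
#'
#' @param target_nifti,confound_nifti 4D NIfTI paths.
#' @param target_mask,confound_mask 3D 0/1 NIfTI paths.
#' @param events_tsv BIDS-style events TSV.
#' @param acquisition an [nf_acquisition()] describing the run; the TR is
#'   cross-checked against the NIfTI header when present.
#' @return an \code{nf_roi_run}.
#' @export
read_roi_run <- function(target_nifti, confound_nifti, target_mask,
                         confound_mask, events_tsv,
                         acquisition = nf_acquisition()) {
  load_roi <- function(img_path, mask_path) {
    img <- RNifti::readNifti(img_path)
    msk <- RNifti::readNifti(mask_path)
    di <- dim(img); dm <- dim(msk)
    if (!identical(di[seq_along(dm)], dm)) {
      stop("shape mismatch between image and mask: ",
           paste(di, collapse = "x"), " vs ", paste(dm, collapse = "x"))
    }
    keep <- which(msk > 0)
    if (length(keep) == 0) stop("empty ROI: mask selects 0 voxels")
    flat <- matrix(img, prod(di[1:3]), di[4])
    flat[keep, , drop = FALSE]
  }
  target <- load_roi(target_nifti, target_mask)
  confound <- load_roi(confound_nifti, confound_mask)
  if (ncol(target) != ncol(confound)) {
    stop("shape mismatch: target and confound differ in volume count")
  }
  ev <- read_events_tsv(events_tsv)
  design <- structure(list(events = ev,
                           rest_duration =
                             unique(ev$duration[ev$trial_type == "rest"])[1],
                           meditation_duration =
                             unique(ev$duration[ev$trial_type ==
                                                  "meditation"])[1],
                           n_rest = sum(ev$trial_type == "rest"),
                           n_meditation =
                             sum(ev$trial_type == "meditation")),
                      class = "nf_block_design")
  structure(list(target = target, confound = confound, design = design,
                 acquisition = acquisition,
                 baseline_target = rowMeans(target),
                 baseline_confound = rowMeans(confound),
                 signal_voxels = integer(0)),
            class = "nf_roi_run")
}

#' Write / read a behavioural cohort as CSV
#'
#' The CSV carries a \code{# session_days:} comment header so the schedule
#' survives the round trip.
#'
#' @param cohort an \code{nf_cohort}.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  days <- attr(cohort, "session_days")
  atomic_write(path, function(p) {
    con <- file(p, "w")
    writeLines(paste0("# session_days: ", paste(days, collapse = ",")), con)
    utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
    close(con)
  })
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  first <- readLines(path, n = 1)
  days <- c(0, 3, 4, 5, 6, 7)
  skip <- 0
  if (startsWith(first, "# session_days:")) {
    days <- as.numeric(strsplit(sub("# session_days: *", "", first),
                                ",")[[1]])
    skip <- 1
  }
  out <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  attr(out, "session_days") <- days
  class(out) <- c("nf_cohort", "data.frame")
  out
}

#' Write a session score log as CSV
#'
#' @param log an \code{nf_session_log}.
#' @param path CSV path.
#' @export
write_session_log <- function(log, path) {
  atomic_write(path, function(p)
    utils::write.csv(as.data.frame(log), p, row.names = FALSE))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config named list.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  atomic_write(path, function(p) yaml::write_yaml(config, p))
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

# per-stage seeds derived from the global seed: stage name hashed to a
# small offset, result kept inside the 32-bit integer range
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
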