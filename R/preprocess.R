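# Resting-state preprocessing on a per-subject BOLD run: initial-volume
# discard, spatial smoothing, nuisance regression, framewise-displacement
# censoring and zero-phase band-pass filtering.

#' Preprocessing configuration
#'
#' @param drop_k initial volumes discarded (default 5).
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (default 6).
#' @param fd_threshold_mm framewise-displacement censoring threshold
#'   (default 1.5 mm).
#' @param min_volumes minimum surviving volumes; below this the run is
#'   excluded (default 50).
#' @param band_low,band_high band-pass edges in Hz (defaults 0.01 and 0.08).
#' @param censor_margin volumes removed on each side of a super-threshold
#'   displacement (default 1: the two volumes bracketing the transition).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(drop_k = 5, fwhm_mm = 6, fd_threshold_mm = 1.5,
                              min_volumes = 50, band_low = 0.01,
                              band_high = 0.08, censor_margin = 1) {
  if (drop_k < 0 || fwhm_mm < 0 || fd_threshold_mm <= 0 || min_volumes < 1 ||
      censor_margin < 1)
    config_error("invalid preprocessing parameters")
  structure(list(drop_k = drop_k, fwhm_mm = fwhm_mm,
                 fd_threshold_mm = fd_threshold_mm, min_volumes = min_volumes,
                 band_low = band_low, band_high = band_high,
                 censor_margin = censor_margin),
            class = "preprocess_config")
}

# Subset a run to a set of current-volume indices (strictly increasing).
subset_volumes <- function(run, keep) {
  run$data <- run$data[, , , keep, drop = FALSE]
  run$motion <- run$motion[keep, , drop = FALSE]
  run$kept_volumes <- run$kept_volumes[keep]
  run
}

#' Discard the initial volumes of a run
#'
#' The first `k` volumes of an acquisition are dropped before any analysis
#' (scanner equilibration).
#'
#' @param run a `bold_run`.
#' @param k number of volumes to discard (default 5).
#' @return the shortened `bold_run`.
#' @export
drop_initial_volumes <- function(run, k = 5) {
  nt <- n_volumes(run)
  if (k < 0) input_error("k must be >= 0")
  if (k >= nt) input_error(sprintf("cannot discard %d of %d volumes", k, nt))
  if (k == 0) return(run)
  subset_volumes(run, (k + 1):nt)
}

# Row-normalized 1D Gaussian convolution matrix (truncated at 3 sigma;
# truncation is renormalized so a constant signal is preserved exactly).
gaussian_band_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  k <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (o in seq_along(offs)) {
    j <- seq_len(n) + offs[o]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[o]
  }
  K / rowSums(K)
}

apply_along_axis1 <- function(arr, K) {
  d <- dim(arr)
  array(K %*% matrix(arr, d[1]), d)
}

#' Spatially smooth each volume with a separable Gaussian kernel
#'
#' Per-axis sigma in voxels is `fwhm / (2 * sqrt(2 * log(2))) / voxel_size`.
#' Edge truncation is renormalized, so a spatially constant volume is
#' unchanged everywhere.
#'
#' @param run a `bold_run`.
#' @param fwhm_mm kernel full width at half maximum in mm (default 6;
#'   0 = identity).
#' @return the smoothed `bold_run`.
#' @export
smooth_gaussian <- function(run, fwhm_mm = 6) {
  if (fwhm_mm < 0) input_error("fwhm must be >= 0")
  if (fwhm_mm == 0) return(run)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$voxel_dim
  d <- dim(run$data)
  arr <- run$data
  arr <- apply_along_axis1(arr, gaussian_band_matrix(d[1], sig[1]))
  arr <- aperm(apply_along_axis1(aperm(arr, c(2, 1, 3, 4)),
                                 gaussian_band_matrix(d[2], sig[2])),
               c(2, 1, 3, 4))
  arr <- aperm(apply_along_axis1(aperm(arr, c(3, 2, 1, 4)),
                                 gaussian_band_matrix(d[3], sig[3])),
               c(3, 2, 1, 4))
  run$data <- arr
  run
}

#' Framewise displacement from a motion trace
#'
#' `FD_t = sum |delta translations| + 50 mm * sum |delta rotations|`, i.e.
#' rotational estimates (radians) are converted to arc displacement at a
#' 50 mm head radius. The first volume has FD 0 by definition.
#'
#' @param motion t x 6 matrix: three translations (mm) then three rotations
#'   (radians).
#' @param rotation_radius_mm conversion radius (default 50).
#' @return numeric vector of per-volume displacements (mm).
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) input_error("motion trace must have 6 columns")
  if (any(!is.finite(motion))) input_error("non-finite motion parameters")
  if (nrow(motion) == 1) return(0)
  dm <- abs(diff(motion))
  c(0, rowSums(dm[, 1:3, drop = FALSE]) +
      rotation_radius_mm * rowSums(dm[, 4:6, drop = FALSE]))
}

#' Censor volumes around super-threshold head movements
#'
#' `FD_t` summarizes the transition from volume t-1 to t; when it exceeds
#' the threshold both bracketing volumes (t-1 and t, extended by
#' `margin - 1` further volumes on each side if configured) are removed.
#' Runs retaining fewer than `min_remaining` volumes yield an exclusion
#' signal instead of a run.
#'
#' @param run a `bold_run`.
#' @param fd framewise-displacement series aligned to the run's volumes.
#' @param threshold_mm censoring threshold (default 1.5 mm).
#' @param min_remaining minimum volumes required (default 50).
#' @param margin volumes removed on each side of a flagged transition
#'   (default 1).
#' @param subject_id identifier forwarded to the exclusion signal.
#' @return the censored `bold_run`, or a `doc_exclusion`.
#' @export
censor_frames <- function(run, fd, threshold_mm = 1.5, min_remaining = 50,
                          margin = 1, subject_id = NA_character_) {
  nt <- n_volumes(run)
  if (length(fd) != nt)
    input_error("fd series is not aligned with the run's volumes")
  bad <- which(fd > threshold_mm)
  drop <- integer(0)
  for (t in bad) drop <- c(drop, (t - margin):(t + margin - 1))
  drop <- sort(unique(pmax(1L, pmin(nt, drop))))
  keep <- setdiff(seq_len(nt), drop)
  if (length(keep) < min_remaining)
    return(exclusion_signal(length(keep), min_remaining, subject_id, fd))
  subset_volumes(run, keep)
}

#' Regress nuisance signals out of every in-mask voxel
#'
#' Design: the 6 motion parameters, their first backward differences, the
#' global mean signal over the brain mask, a linear trend, and an intercept.
#' Residuals are numerically orthogonal to every retained regressor.
#' Rank-deficient designs drop the aliased columns with a warning.
#' Out-of-mask voxels are left untouched.
#'
#' @param run a `bold_run`.
#' @return the residualized `bold_run`.
#' @export
nuisance_regress <- function(run) {
  nt <- n_volumes(run)
  d <- dim(run$data)
  vox <- matrix(run$data, prod(d[1:3]), nt)
  inmask <- which(run$mask)
  Y <- t(vox[inmask, , drop = FALSE])           # t x V
  global <- rowMeans(Y)
  diffs <- rbind(0, diff(run$motion))
  X <- cbind(intercept = 1, run$motion, diffs, global = global,
             trend = seq_len(nt) - (nt + 1) / 2)
  fit <- stats::lm.fit(X, Y)
  if (any(is.na(fit$coefficients)))
    warning("rank-deficient nuisance design; collinear columns dropped")
  vox[inmask, ] <- t(fit$residuals)
  run$data <- array(vox, d)
  run
}

#' Zero-phase band-pass filter on the retained series
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) per in-mask voxel, on the concatenated retained
#' series. The acceptance contract is the amplitude response: a 0.04 Hz
#' component of an uncensored TR = 2 s series retains at least 90% of its
#' amplitude; a 0.2 Hz component retains at most 10%.
#'
#' @param run a `bold_run`.
#' @param low,high passband edges in Hz (defaults 0.01 and 0.08).
#' @param order Butterworth section order (default 2).
#' @return the filtered `bold_run`.
#' @export
bandpass_filter <- function(run, low = 0.01, high = 0.08, order = 2) {
  fs <- 1 / run$tr
  if (high <= low || high >= fs / 2)
    config_error("band edges must satisfy 0 < low < high < Nyquist")
  nt <- n_volumes(run)
  if (nt < 8) input_error("band-pass filtering needs at least 8 volumes")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- dim(run$data)
  vox <- matrix(run$data, prod(d[1:3]), nt)
  inmask <- which(run$mask)
  filt <- apply(vox[inmask, , drop = FALSE], 1,
                function(v) signal::filtfilt(bf, v - mean(v)))
  vox[inmask, ] <- t(filt)
  run$data <- array(vox, d)
  run
}

#' Run the full preprocessing chain on one BOLD run
#'
#' Stage order: discard initial volumes, smooth, nuisance-regress, censor by
#' framewise displacement, band-pass filter the surviving series. Returns an
#' exclusion signal when censoring leaves fewer than the configured minimum
#' number of volumes. The chain is fully deterministic.
#'
#' @param run a `bold_run`.
#' @param config a [preprocess_config()].
#' @param subject_id identifier used in QC output.
#' @return the preprocessed `bold_run` (with a `qc` attribute summarizing
#'   retention), or a `doc_exclusion`.
#' @export
preprocess_run <- function(run, config = preprocess_config(),
                           subject_id = NA_character_) {
  run <- drop_initial_volumes(run, config$drop_k)
  run <- smooth_gaussian(run, config$fwhm_mm)
  run <- nuisance_regress(run)
  fd <- compute_fd(run$motion)
  run <- censor_frames(run, fd, config$fd_threshold_mm, config$min_volumes,
                       config$censor_margin, subject_id)
  if (is_excluded(run)) return(run)
  n_censored <- length(fd) - n_volumes(run)
  run <- bandpass_filter(run, config$band_low, config$band_high)
  attr(run, "qc") <- list(subject_id = subject_id, fd_max = max(fd),
                          fd_mean = mean(fd), n_censored = n_censored,
                          volumes_retained = n_volumes(run))
  run
}
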