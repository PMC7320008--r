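# internal: Butterworth band-pass design for a given frame period.
# `order` is the overall analog prototype order (even); signal::butter() takes
# the low-pass prototype order, which is order/2 for a band-pass.
band_filter <- function(frame_period, f_lo = 0.05, f_hi = 0.2, order = 4) {
  nyq <- 0.5 / frame_period
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq)) {
    fus_abort(sprintf(
      "band [%g, %g] Hz is invalid for Nyquist %g Hz.", f_lo, f_hi, nyq
    ), class = "fusfc_bad_band")
  }
  if (order %% 2 != 0 || order < 2) {
    fus_abort("`order` must be an even integer >= 2.")
  }
  signal::butter(order / 2, c(f_lo, f_hi) / nyq, type = "pass")
}

#' Zero-phase band-pass filter of ROI signals
#'
#' Applies a Butterworth band-pass (default 4th order, resting-state band
#' 0.05-0.2 Hz) forward and backward (`signal::filtfilt`), giving zero phase
#' distortion — essential for the downstream instantaneous-phase analysis.
#' The row mean is removed before filtering.
#'
#' @param series An [roi_series()].
#' @param f_lo,f_hi Band edges in Hz (defaults 0.05 and 0.2).
#' @param order Overall filter order (even, default 4).
#' @return The filtered `roi_series` (full length; edge transients are
#'   absorbed by the dynamic stage's 100-sample truncation).
#' @export
bandpass <- function(series, f_lo = 0.05, f_hi = 0.2, order = 4) {
  stopifnot(inherits(series, "roi_series"))
  bf <- band_filter(frame_period(series), f_lo, f_hi, order)
  x <- series_matrix(series)
  xf <- apply(x, 2, function(v) signal::filtfilt(bf, v - mean(v)))
  replace_signals(series, xf)
}

#' Normalize each ROI signal by the square root of its energy
#'
#' Divides each ROI's signal by `sqrt(sum(x^2))`, so every ROI has unit
#' energy. Pearson correlations are invariant to this scaling; it fixes the
#' scale of the analytic signal for the phase stage.
#'
#' @inheritParams bandpass
#' @return The normalized `roi_series`, flagged `preprocessed`.
#' @export
normalize_energy <- function(series) {
  stopifnot(inherits(series, "roi_series"))
  x <- series_matrix(series)
  en <- colSums(x^2)
  if (any(en == 0)) {
    fus_abort(sprintf(
      "ROI(s) with all-zero signal cannot be normalized: %s.",
      paste(colnames(x)[en == 0], collapse = ", ")
    ), class = "fusfc_zero_signal")
  }
  replace_signals(series, sweep(x, 2, sqrt(en), "/"), preprocessed = TRUE)
}

#' Band-pass + energy normalization in one step
#' @inheritParams bandpass
#' @return A preprocessed `roi_series`.
#' @export
preprocess <- function(series, f_lo = 0.05, f_hi = 0.2, order = 4) {
  normalize_energy(bandpass(series, f_lo, f_hi, order))
}

#' Spatially average a Doppler movie over ROI masks
#'
#' @param movie A `fus_movie` (see [simulate_doppler_movie()]).
#' @param roi_masks Named list of logical matrices; defaults to the movie's
#'   own masks.
#' @return A raw [roi_series()], one column per mask.
#' @export
extract_roi_signals <- function(movie, roi_masks = movie$roi_masks) {
  stopifnot(inherits(movie, "fus_movie"))
  if (is.null(roi_masks) || !length(roi_masks)) {
    fus_abort("`roi_masks` must be a non-empty named list of masks.")
  }
  nz <- dim(movie$data)[1]; nx <- dim(movie$data)[2]
  nt <- dim(movie$data)[3]
  flat <- matrix(movie$data, nz * nx, nt)
  sig <- purrr::imap(roi_masks, function(m, lab) {
    if (!any(m)) {
      fus_abort(sprintf("ROI mask '%s' covers zero pixels.", lab),
                class = "fusfc_empty_mask")
    }
    if (any(m & !movie$brain_mask)) {
      fus_abort(sprintf("ROI mask '%s' leaves the brain mask.", lab))
    }
    colMeans(flat[which(m), , drop = FALSE])
  })
  roi_series(do.call(cbind, sig), movie$frame_period,
             roi_labels = names(roi_masks))
}

#' Zero-phase band-pass filter of every brain pixel of a movie
#'
#' @inheritParams extract_roi_signals
#' @inheritParams bandpass
#' @return The movie with filtered pixel traces (non-brain pixels zeroed) and
#'   attribute `preprocessed = TRUE`.
#' @export
bandpass_movie <- function(movie, f_lo = 0.05, f_hi = 0.2, order = 4) {
  stopifnot(inherits(movie, "fus_movie"))
  bf <- band_filter(movie$frame_period, f_lo, f_hi, order)
  nz <- dim(movie$data)[1]; nx <- dim(movie$data)[2]
  nt <- dim(movie$data)[3]
  flat <- matrix(movie$data, nz * nx, nt)
  px <- which(movie$brain_mask)
  out <- matrix(0, nz * nx, nt)
  for (p in px) {
    v <- flat[p, ]
    out[p, ] <- signal::filtfilt(bf, v - mean(v))
  }
  movie$data <- array(out, c(nz, nx, nt))
  attr(movie, "preprocessed") <- TRUE
  movie
}
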