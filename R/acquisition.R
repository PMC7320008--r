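#' Derive the full fUS acquisition geometry from its primitive parameters
#'
#' A functional-ultrasound acquisition is parameterised by the power-Doppler
#' frame period, the total acquisition duration, the compound-image rate and
#' the span of tilted plane-wave angles. Every derived count (frames per
#' acquisition, compound images per frame, number of plane-wave angles, pulse
#' repetition frequency) follows by exact arithmetic; this function fills them
#' in and refuses configurations whose derived counts are not integers.
#'
#' @param frame_period Power-Doppler frame period in seconds (default 0.4).
#' @param duration Total acquisition duration in seconds (default 600).
#' @param compound_rate Compound-image rate in Hz (default 500).
#' @param angle_min,angle_max,angle_step Plane-wave tilt angle span and step,
#'   in degrees (defaults -10, +10, 2).
#'
#' @return An object of class `fus_acquisition`: a list with the inputs plus
#'   `n_frames`, `compounds_per_frame`, `n_angles` and `prf` (in kHz).
#' @examples
#' acq <- acquisition_geometry()
#' acq$n_frames             # 1500
#' acq$compounds_per_frame  # 200
#' acq$prf                  # 5.5 kHz
#' @export
acquisition_geometry <- function(frame_period = 0.4,
                                 duration = 600,
                                 compound_rate = 500,
                                 angle_min = -10,
                                 angle_max = 10,
                                 angle_step = 2) {
  check_number(frame_period, "frame_period")
  check_number(duration, "duration")
  check_number(compound_rate, "compound_rate")
  check_number(angle_step, "angle_step")
  if (!is.numeric(angle_min) || !is.numeric(angle_max) ||
      angle_max <= angle_min) {
    fus_abort("`angle_max` must exceed `angle_min`.")
  }

  as_exact_int <- function(x, field) {
    r <- round(x)
    if (abs(x - r) > 1e-9) {
      fus_abort(sprintf(
        "`%s` = %g is not an integer; check the acquisition parameters.",
        field, x
      ), class = "fusfc_noninteger")
    }
    as.integer(r)
  }

  out <- list(
    frame_period = frame_period,
    duration = duration,
    compound_rate = compound_rate,
    angle_min = angle_min,
    angle_max = angle_max,
    angle_step = angle_step,
    n_frames = as_exact_int(duration / frame_period, "n_frames"),
    compounds_per_frame = as_exact_int(
      compound_rate * frame_period, "compounds_per_frame"
    ),
    n_angles = as_exact_int(
      (angle_max - angle_min) / angle_step + 1, "n_angles"
    )
  )
  out$prf <- out$n_angles * compound_rate / 1000
  structure(out, class = "fus_acquisition")
}

#' @export
print.fus_acquisition <- function(x, ...) {
  cat("<fus_acquisition>\n")
  cat(sprintf(
    "  %g s acquisition, %g s/frame -> %d frames\n",
    x$duration, x$frame_period, x$n_frames
  ))
  cat(sprintf(
    "  %g Hz compounding -> %d compound images/frame\n",
    x$compound_rate, x$compounds_per_frame
  ))
  cat(sprintf(
    "  plane waves %g..%g deg step %g -> %d angles, PRF %g kHz\n",
    x$angle_min, x$angle_max, x$angle_step, x$n_angles, x$prf
  ))
  invisible(x)
}
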