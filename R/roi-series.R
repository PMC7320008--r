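#' Construct an ROI time-series table
#'
#' The central currency of the pipeline: one row per power-Doppler frame, a
#' `time` column in seconds, and one column per ROI carrying its mean
#' hemodynamic (CBV) signal. Sampling and animal metadata travel as
#' attributes.
#'
#' @param signals Numeric matrix (frames x ROIs) or data frame of ROI signals.
#' @param frame_period Frame period in seconds.
#' @param roi_labels ROI labels; default taken from column names.
#' @param animal_id,group,cohort Optional metadata labels.
#' @param preprocessed Logical: has the band-pass + energy normalization been
#'   applied?
#' @return A tibble of class `roi_series`.
#' @export
roi_series <- function(signals, frame_period,
                       roi_labels = colnames(signals),
                       animal_id = NA_character_,
                       group = NA_character_,
                       cohort = NA_character_,
                       preprocessed = FALSE) {
  signals <- as.matrix(signals)
  check_number(frame_period, "frame_period")
  if (is.null(roi_labels)) {
    roi_labels <- sprintf("ROI_%02d", seq_len(ncol(signals)))
  }
  if (length(roi_labels) != ncol(signals) || anyDuplicated(roi_labels)) {
    fus_abort("`roi_labels` must be unique, one per signal column.")
  }
  colnames(signals) <- roi_labels
  out <- as_tibble(signals)
  out <- dplyr::mutate(
    out,
    time = (dplyr::row_number() - 1) * frame_period,
    .before = 1
  )
  new_roi_series(out, frame_period, animal_id, group, cohort, preprocessed)
}

new_roi_series <- function(tbl, frame_period, animal_id, group, cohort,
                           preprocessed) {
  structure(
    tbl,
    frame_period = frame_period,
    animal_id = animal_id,
    group = group,
    cohort = cohort,
    preprocessed = preprocessed,
    class = c("roi_series", class(tibble()))
  )
}

#' Extract the signal matrix (frames x ROIs) from an `roi_series`
#' @param series An [roi_series()] table.
#' @return A numeric matrix with one column per ROI.
#' @export
series_matrix <- function(series) {
  stopifnot(inherits(series, "roi_series"))
  as.matrix(series[setdiff(names(series), "time")])
}

#' ROI labels of an `roi_series`
#' @inheritParams series_matrix
#' @export
roi_labels <- function(series) setdiff(names(series), "time")

#' Frame period (seconds) of an `roi_series`
#' @inheritParams series_matrix
#' @export
frame_period <- function(series) attr(series, "frame_period")

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf(
    "<roi_series> %s | %d frames x %d ROIs @ %g s/frame | %s\n",
    attr(x, "animal_id") %||% "?", nrow(x), ncol(x) - 1L,
    attr(x, "frame_period"),
    if (isTRUE(attr(x, "preprocessed"))) "preprocessed" else "raw"
  ))
  NextMethod()
}

# internal: rebuild an roi_series with a new signal matrix, keeping metadata
replace_signals <- function(series, mat, preprocessed = NULL) {
  tbl <- as_tibble(cbind(time = series$time, as.data.frame(mat)))
  new_roi_series(
    tbl,
    frame_period = attr(series, "frame_period"),
    animal_id = attr(series, "animal_id"),
    group = attr(series, "group"),
    cohort = attr(series, "cohort"),
    preprocessed = preprocessed %||% attr(series, "preprocessed")
  )
}
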