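#' Write / read ROI time series as CSV
#'
#' Column 1 is `time` in seconds; remaining columns are the ROI signals,
#' one per label. Metadata (frame period, animal, group, cohort,
#' preprocessed flag) travels in a JSON sidecar `<path>.json`.
#'
#' @param series An [roi_series()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(series, path) {
  stopifnot(inherits(series, "roi_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  meta <- list(
    frame_period = frame_period(series),
    animal_id = attr(series, "animal_id"),
    group = attr(series, "group"),
    cohort = attr(series, "cohort"),
    preprocessed = isTRUE(attr(series, "preprocessed"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_series
#' @param frame_period Frame period in seconds; only needed if no JSON
#'   sidecar exists.
#' @export
read_roi_series <- function(path, frame_period = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fp <- meta$frame_period %||% frame_period
  if (is.null(fp)) {
    fp <- if (nrow(df) > 1) diff(df$time[1:2]) else
      fus_abort("frame period unknown; pass `frame_period`.")
  }
  roi_series(
    as.matrix(df[setdiff(names(df), "time")]),
    frame_period = fp,
    animal_id = meta$animal_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    cohort = meta$cohort %||% NA_character_,
    preprocessed = isTRUE(meta$preprocessed)
  )
}

#' Write a simulated cohort to a directory
#'
#' Per-animal ROI series as CSV (+ JSON sidecars), the behaviour table as
#' CSV, and a manifest JSON with group/cohort labels and the planted ground
#' truth (state sequences, latent severities).
#'
#' @param cohort A `fus_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk2(cohort$series, cohort$animal_id, function(s, id) {
    write_roi_series(s, file.path(dir, paste0(id, ".csv")))
  })
  utils::write.csv(
    as.data.frame(behavior_table(cohort)),
    file.path(dir, "behavior.csv"), row.names = FALSE
  )
  manifest <- list(
    animals = purrr::pmap(
      list(cohort$animal_id, cohort$group, cohort$cohort,
           cohort$severity, cohort$state_seq),
      function(id, g, co, sev, st) {
        list(animal_id = id, group = g, cohort = co,
             severity = sev, state_seq = as.integer(st))
      }
    )
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  rows <- purrr::map(manifest$animals, function(a) {
    tibble(
      animal_id = a$animal_id, group = a$group, cohort = a$cohort,
      severity = a$severity,
      state_seq = list(as.integer(unlist(a$state_seq))),
      series = list(read_roi_series(
        file.path(dir, paste0(a$animal_id, ".csv"))
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  beh <- as_tibble(utils::read.csv(file.path(dir, "behavior.csv")))
  beh$animal_id <- as.character(beh$animal_id)
  out <- dplyr::left_join(out, dplyr::select(beh, -"group"), by = "animal_id")
  structure(out, class = c("fus_cohort", class(tibble())))
}

#' Write / read a Doppler movie as a flat binary array with JSON sidecar
#'
#' The pixel data are stored as little-endian doubles in column-major
#' (z, x, t) order; `<path>.json` records shape, dtype, byte order and frame
#' period. Masks are stored inside the sidecar as 0/1 matrices.
#'
#' @param movie A `fus_movie`.
#' @param path Binary file path (sidecar written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "fus_movie"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(movie$data), con, size = 8, endian = "little")
  meta <- list(
    shape = dim(movie$data),
    dtype = "float64",
    order = "column-major (z, x, t)",
    endian = "little",
    frame_period = movie$frame_period,
    brain_mask = unclass(movie$brain_mask * 1L),
    roi_masks = purrr::map(movie$roi_masks, function(m) unclass(m * 1L))
  )
  jsonlite::write_json(
    meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  dat <- readBin(con, "double", n = prod(shape), size = 8, endian = "little")
  masks <- purrr::map(meta$roi_masks, function(m) {
    matrix(as.logical(m), shape[1], shape[2])
  })
  structure(
    list(
      data = array(dat, shape),
      brain_mask = matrix(as.logical(meta$brain_mask), shape[1], shape[2]),
      roi_masks = masks,
      frame_period = meta$frame_period
    ),
    class = "fus_movie"
  )
}

#' Write a significance or Spearman table as long-format CSV
#' @param x A tibble (e.g. from [significance_matrix()]) or a
#'   `spearman_blocks` object (tidied first).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  if (inherits(x, "spearman_blocks")) x <- tidy(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
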