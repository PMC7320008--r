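#' Simulate a planted brain-state label sequence
#'
#' Draws a first-order Markov chain over the configured states, starting from
#' the stationary distribution of the group's transition matrix.
#'
#' @param config A [cohort_config()].
#' @param group `"control"` or `"arthritic"` (selects the transition matrix).
#' @param n_frames Sequence length; defaults to the acquisition frame count.
#' @param init Optional fixed start state; by default the start state is
#'   drawn from the stationary distribution of the transition matrix.
#' @return Integer vector of state indices.
#' @export
simulate_state_sequence <- function(config, group = c("control", "arthritic"),
                                    n_frames = config$acquisition$n_frames,
                                    init = NULL) {
  group <- match.arg(group)
  P <- if (group == "control") config$transition_control else
    config$transition_arthritic
  k <- length(config$states)
  check_transition(P, k)
  s <- integer(n_frames)
  s[1] <- if (!is.null(init)) as.integer(init) else {
    sample.int(k, 1L, prob = stationary_distribution(P))
  }
  # cumulative rows once; inverse-CDF draws keep the loop cheap
  cs <- t(apply(P, 1, cumsum))
  u <- runif(n_frames)
  for (i in seq_len(n_frames - 1L)) {
    s[i + 1L] <- findInterval(u[i], cs[s[i], ]) + 1L
  }
  s
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}

# internal: per-frame phase offsets with a linear ramp at each switch
state_phase_track <- function(states, state_seq, ramp) {
  offs <- do.call(rbind, purrr::map(states, "phase_offsets"))
  th <- offs[state_seq, , drop = FALSE]
  if (ramp > 0) {
    sw <- which(diff(state_seq) != 0L)
    n <- length(state_seq)
    for (s in sw) {
      a <- offs[state_seq[s], ]
      b <- offs[state_seq[s + 1L], ]
      idx <- s + seq_len(ramp)
      idx <- idx[idx <= n]
      for (j in seq_along(idx)) {
        th[idx[j], ] <- a + (b - a) * j / (ramp + 1)
      }
    }
  }
  th
}

#' Simulate ROI hemodynamic signals for one animal
#'
#' Each ROI carries a shared narrow-band carrier whose phase offset follows
#' the planted state sequence (interpolated over a short ramp at switches),
#' plus white measurement noise. In arthritic animals the shared-carrier
#' amplitude of the designated sub-network ROIs is attenuated in proportion
#' to the animal's latent severity, and the lost variance is replaced by an
#' independent band-limited private component, so that the pairwise
#' correlation of an attenuated ROI scales with the attenuation factor while
#' total signal power is preserved.
#'
#' @inheritParams simulate_state_sequence
#' @param state_seq Integer state sequence from [simulate_state_sequence()].
#' @param severity Latent severity in \[0, 1\] (0 for controls).
#' @param animal_id,cohort Metadata labels attached to the result.
#' @return A raw (unpreprocessed) [roi_series()].
#' @export
simulate_roi_signals <- function(config, state_seq,
                                 group = c("control", "arthritic"),
                                 severity = 0,
                                 animal_id = NA_character_,
                                 cohort = "test") {
  group <- match.arg(group)
  acq <- config$acquisition
  nyq <- 0.5 / acq$frame_period
  if (config$carrier_freq <= 0 || config$carrier_freq >= nyq) {
    fus_abort(sprintf(
      "`carrier_freq` must lie in (0, %g) Hz for a %g s frame period.",
      nyq, acq$frame_period
    ))
  }
  if (severity < 0 || severity > 1) {
    fus_abort("`severity` must lie in [0, 1].")
  }
  n <- length(state_seq)
  tt <- (seq_len(n) - 1L) * acq$frame_period
  th <- state_phase_track(config$states, state_seq, config$ramp)

  sev_mean <- mean(config$severity_range)
  w <- rep(1, config$n_roi)
  if (group == "arthritic" && config$subnetwork_attenuation < 1) {
    idx <- match(config$attenuated_rois, config$roi_labels)
    w[idx] <- pmin(pmax(
      1 - (1 - config$subnetwork_attenuation) * severity / sev_mean,
      0.05
    ), 1)
  }

  bf <- band_filter(acq$frame_period)
  x <- matrix(0, n, config$n_roi)
  for (j in seq_len(config$n_roi)) {
    shared <- cos(2 * pi * config$carrier_freq * tt + th[, j])
    xj <- w[j] * shared
    if (w[j] < 1) {
      eta <- signal::filtfilt(bf, rnorm(n))
      eta <- eta / stats::sd(eta) / sqrt(2) # match carrier RMS
      xj <- xj + sqrt(1 - w[j]^2) * eta
    }
    x[, j] <- xj + rnorm(n, 0, config$noise_sd)
  }
  colnames(x) <- config$roi_labels
  out <- roi_series(
    x, acq$frame_period,
    animal_id = animal_id, group = group, cohort = cohort
  )
  attr(out, "carrier_weight") <- setNames(w, config$roi_labels)
  out
}

#' Simulate behavioural measures from latent severity
#'
#' Generates the six behavioural variables (weight gain, inflammation score,
#' left/right von Frey thresholds, left/right foot-bend scores). Group means
#' default to the generative targets (control weight gain 136.00 g vs
#' arthritic 49.44 g; inflammation medians 0 vs 22); within-group variation is
#' driven by the latent severity through the `behavior_link` loadings, so
#' connectivity alterations and behaviour are correlated by construction.
#' Bounded scores are clipped to their valid ranges.
#'
#' @inheritParams simulate_state_sequence
#' @param severity Numeric vector of latent severities in \[0, 1\]
#'   (0 for controls).
#' @param group Character vector (`"control"`/`"arthritic"`), one per animal.
#' @param animal_id Animal identifiers.
#' @return A tibble with one row per animal.
#' @export
simulate_behavior <- function(config, severity, group,
                              animal_id = seq_along(severity)) {
  if (any(severity < 0 | severity > 1)) {
    fus_abort("`severity` values must lie in [0, 1].")
  }
  if (length(group) != length(severity)) {
    fus_abort("`group` and `severity` must have the same length.")
  }
  lam <- config$behavior_link
  bs <- config$behavior_noise_scale
  sev_mean <- mean(config$severity_range)
  n <- length(severity)
  eff <- function(var) lam[[var]] * severity / sev_mean
  ctrl <- group == "control"

  wg_sd <- ifelse(ctrl, 35.28, 30.5) # arthritic residual after severity spread
  weight_gain <- 136.00 - 86.56 * eff("weight_gain") + rnorm(n, 0, wg_sd * bs)
  inflammation <- pmin(pmax(round(
    22 * eff("inflammation_score") + rnorm(n, 0, 3 * bs)
  ), 0), 60)
  vf <- function(var) {
    pmax(250 - 120 * eff(var) + rnorm(n, 0, 25 * bs), 1)
  }
  bend <- function(var) {
    pmin(pmax(round(4 * eff(var) + rnorm(n, 0, 0.5 * bs)), 0), 5)
  }
  tibble(
    animal_id = as.character(animal_id),
    group = group,
    weight_gain = weight_gain,
    inflammation_score = as.integer(inflammation),
    vonfrey_left = vf("vonfrey_left"),
    vonfrey_right = vf("vonfrey_right"),
    bend_left = as.integer(bend("bend_left")),
    bend_right = as.integer(bend("bend_right"))
  )
}

#' Simulate a full ground-truth-known cohort
#'
#' Runs the Markov state-switching oscillator for every animal of both groups
#' and attaches behaviour driven by the same latent severity. The result is a
#' tibble with one row per animal: metadata, the planted ground truth
#' (severity, state sequence, carrier weights) and the raw ROI series as a
#' list-column. Identical config + seed gives a bit-identical cohort.
#'
#' @param config A [cohort_config()]; `config$seed` seeds all randomness.
#' @param cohort Cohort label attached to every animal (default `"test"`).
#' @return A tibble of class `fus_cohort`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_control = 2, n_arthritic = 2))
#' coh$series[[1]]
#' @export
simulate_cohort <- function(config, cohort = "test") {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(config$seed)
  groups <- rep(c("control", "arthritic"),
                c(config$n_control, config$n_arthritic))
  ids <- c(
    sprintf("C%02d", seq_len(config$n_control)),
    sprintf("A%02d", seq_len(config$n_arthritic))
  )
  severity <- ifelse(
    groups == "control", 0,
    runif(length(groups), config$severity_range[1], config$severity_range[2])
  )
  rows <- purrr::map(seq_along(ids), function(i) {
    st <- simulate_state_sequence(config, groups[i])
    ser <- simulate_roi_signals(
      config, st, groups[i],
      severity = severity[i], animal_id = ids[i], cohort = cohort
    )
    list(state_seq = st, series = ser)
  })
  beh <- simulate_behavior(config, severity, groups, animal_id = ids)
  out <- tibble(
    animal_id = ids,
    group = groups,
    cohort = cohort,
    severity = severity,
    state_seq = purrr::map(rows, "state_seq"),
    series = purrr::map(rows, "series")
  )
  out <- dplyr::left_join(out, dplyr::select(beh, -"group"), by = "animal_id")
  structure(out, config = config,
            class = c("fus_cohort", class(tibble())))
}

#' Behaviour table of a cohort
#' @param cohort A `fus_cohort` from [simulate_cohort()].
#' @return A tibble (animal_id, group, behavioural variables).
#' @export
behavior_table <- function(cohort) {
  dplyr::select(
    as_tibble(cohort),
    "animal_id", "group", dplyr::all_of(behavior_variables())
  )
}

#' Animal-to-group mapping of a cohort
#' @inheritParams behavior_table
#' @return A tibble (animal_id, group, cohort).
#' @export
group_table <- function(cohort) {
  dplyr::select(as_tibble(cohort), "animal_id", "group", "cohort")
}

#' Rectangular ROI label masks on a small image grid
#'
#' Lays `n_roi` disjoint rectangular masks on an `n_z` x `n_x` grid inside a
#' rectangular brain mask, for synthetic Doppler movies.
#'
#' @param n_roi Number of ROIs.
#' @param n_z,n_x Grid size (default 40 x 64, smaller than a full acquisition
#'   for speed; any size can be requested).
#' @param labels ROI labels.
#' @return List with `brain_mask` (logical matrix) and `roi_masks` (named list
#'   of logical matrices).
#' @export
default_roi_masks <- function(n_roi = 10, n_z = 40, n_x = 64,
                              labels = default_roi_labels(n_roi)) {
  brain <- matrix(FALSE, n_z, n_x)
  brain[3:(n_z - 2), 3:(n_x - 2)] <- TRUE
  per_row <- ceiling(n_roi / 2)
  w <- (n_x - 8) %/% per_row
  h <- (n_z - 8) %/% 2
  if (w < 2 || h < 1) fus_abort("grid too small for this many ROIs.")
  masks <- purrr::map(seq_len(n_roi), function(i) {
    r <- (i - 1) %/% per_row
    c0 <- 4 + ((i - 1) %% per_row) * w
    r0 <- 4 + r * h
    m <- matrix(FALSE, n_z, n_x)
    m[r0:(r0 + max(1, h %/% 2) - 1), c0:(c0 + max(1, w %/% 2) - 1)] <- TRUE
    m & brain
  })
  list(brain_mask = brain, roi_masks = setNames(masks, labels))
}

#' Simulate a pixel-level power-Doppler movie from ROI signals
#'
#' Every pixel of an ROI carries that ROI's signal plus independent pixel
#' noise; brain pixels outside any ROI carry independent noise only.
#'
#' @param roi_set An [roi_series()] (raw signals).
#' @param roi_masks Named list of logical matrices, one per ROI in `roi_set`.
#' @param brain_mask Logical matrix; all ROI masks must lie inside it.
#' @param pixel_noise_sd Independent per-pixel noise SD.
#' @return An object of class `fus_movie`: list with `data`
#'   (`n_z x n_x x n_t`), `brain_mask`, `roi_masks`, `frame_period`.
#' @export
simulate_doppler_movie <- function(roi_set, roi_masks, brain_mask,
                                   pixel_noise_sd = 0.1) {
  labs <- roi_labels(roi_set)
  if (!all(labs %in% names(roi_masks))) {
    fus_abort("`roi_masks` must contain a mask for every ROI in `roi_set`.")
  }
  roi_masks <- roi_masks[labs]
  empty <- purrr::map_lgl(roi_masks, function(m) !any(m))
  if (any(empty)) {
    fus_abort(sprintf(
      "ROI mask(s) cover zero pixels: %s.",
      paste(labs[empty], collapse = ", ")
    ), class = "fusfc_empty_mask")
  }
  cover <- Reduce(`+`, roi_masks)
  if (any(cover > 1)) {
    fus_abort("ROI masks overlap.", class = "fusfc_overlap_mask")
  }
  if (any(purrr::map_lgl(roi_masks, function(m) any(m & !brain_mask)))) {
    fus_abort("ROI masks must lie inside the brain mask.")
  }
  sig <- series_matrix(roi_set)
  nt <- nrow(sig)
  nz <- nrow(brain_mask); nx <- ncol(brain_mask)
  dat <- array(0, c(nz, nx, nt))
  noise_px <- which(brain_mask & cover == 0)
  for (t in seq_len(nt)) {
    fr <- matrix(0, nz, nx)
    fr[noise_px] <- rnorm(length(noise_px), 0, pixel_noise_sd)
    dat[, , t] <- fr
  }
  for (j in seq_along(roi_masks)) {
    px <- which(roi_masks[[j]])
    for (p in px) {
      zi <- (p - 1) %% nz + 1
      xi <- (p - 1) %/% nz + 1
      dat[zi, xi, ] <- sig[, j] + rnorm(nt, 0, pixel_noise_sd)
    }
  }
  structure(
    list(
      data = dat, brain_mask = brain_mask, roi_masks = roi_masks,
      frame_period = frame_period(roi_set)
    ),
    class = "fus_movie"
  )
}
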