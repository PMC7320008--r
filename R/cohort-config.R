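#' Phase-offset specification of a planted brain state
#'
#' A planted brain state is a vector of per-ROI phase offsets (radians) of the
#' shared narrow-band carrier. The first ROI is the phase reference and must
#' have offset 0; offsets live in (-pi, pi].
#'
#' @param phase_offsets Numeric vector of per-ROI offsets in radians.
#' @param label Optional state label.
#' @return A `state_spec` list with elements `phase_offsets` and `label`.
#' @export
state_spec <- function(phase_offsets, label = NULL) {
  if (!is.numeric(phase_offsets) || length(phase_offsets) < 2) {
    fus_abort("`phase_offsets` must be a numeric vector (one entry per ROI).")
  }
  if (abs(phase_offsets[1]) > 1e-12) {
    fus_abort("the reference ROI (first entry) must have phase offset 0.")
  }
  if (any(phase_offsets <= -pi - 1e-12 | phase_offsets > pi + 1e-12)) {
    fus_abort("phase offsets must lie in (-pi, pi].")
  }
  structure(
    list(phase_offsets = as.numeric(phase_offsets), label = label),
    class = "state_spec"
  )
}

#' Default planted brain states for a 10-ROI bilateral cortical plane
#'
#' Five binary antiphase patterns over the 10 default ROIs: a global in-phase
#' state, a left/right hemispheric split, a somatomotor-vs-cingulate split, a
#' motor-vs-rest split, and a mixed pattern. Binary 0/pi offsets put the
#' per-frame phase-locking values at +/-1, which makes the planted states
#' exactly identifiable by L1 clustering at low noise.
#'
#' @param n_roi Number of ROIs (patterns are defined for 10; other counts get
#'   the patterns truncated/recycled).
#' @return A list of 5 [state_spec()] objects.
#' @export
default_states <- function(n_roi = 10) {
  base <- rbind(
    in_phase     = rep(0, 10),
    hemispheric  = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    cingulate    = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
    motor        = c(0, 0, 1, 1, 1, 1, 0, 0, 0, 0),
    mixed        = c(0, 1, 1, 0, 0, 1, 1, 0, 0, 1)
  ) * pi
  pats <- base[, rep_len(seq_len(10), n_roi), drop = FALSE]
  pats[, 1] <- 0
  purrr::map(seq_len(nrow(pats)), function(i) {
    state_spec(pats[i, ], label = rownames(base)[i])
  })
}

#' Build a state transition matrix from a target occupancy
#'
#' Constructs the row-stochastic first-order Markov transition matrix
#' `P = (1 - 1/dwell_scale) I + (1/dwell_scale) 1 pi'`, whose stationary
#' distribution is exactly the target occupancy `pi` and whose switching
#' probability per frame is `1/dwell_scale`.
#'
#' @param occupancy Target stationary occupancy (non-negative, sums to 1).
#' @param dwell_scale Mean number of frames between switch opportunities.
#' @return A row-stochastic matrix.
#' @export
transition_from_occupancy <- function(occupancy, dwell_scale = 50) {
  if (any(occupancy < 0) || abs(sum(occupancy) - 1) > 1e-8) {
    fus_abort("`occupancy` must be non-negative and sum to 1.")
  }
  check_number(dwell_scale, "dwell_scale")
  k <- length(occupancy)
  p <- 1 / dwell_scale
  (1 - p) * diag(k) + p * matrix(occupancy, k, k, byrow = TRUE)
}

default_roi_labels <- function(n_roi = 10) {
  base <- c(
    "S1HL_L", "S1HL_R", "M1_L", "M1_R", "M2_L",
    "M2_R", "Cg1_L", "Cg1_R", "Cg2_L", "Cg2_R"
  )
  if (n_roi <= 10) base[seq_len(n_roi)] else
    c(base, sprintf("ROI_%02d", seq_len(n_roi - 10) + 10))
}

#' Configuration of a synthetic fUS cohort
#'
#' Bundles every parameter of the Markov state-switching oscillator that
#' generates ground-truth-known cohorts: ROI layout, group sizes, the shared
#' carrier and noise level, the planted brain states and their group-specific
#' transition matrices, the arthritic sub-network attenuation, and the
#' loadings that tie behavioural variables to the latent severity driving the
#' connectivity alterations.
#'
#' @param n_roi Number of ROIs (default 10).
#' @param roi_labels ROI labels (default: bilateral S1HL, M1, M2, Cg1, Cg2).
#' @param n_control,n_arthritic Animals per group (default 9 and 9).
#' @param carrier_freq Shared-carrier frequency in Hz; must sit inside the
#'   resting-state band (default 0.08).
#' @param noise_sd White measurement-noise SD in units of the unit carrier
#'   amplitude (default 0.1).
#' @param states List of [state_spec()] planted states.
#' @param transition_control,transition_arthritic Row-stochastic transition
#'   matrices over the states, one per group. Defaults: occupancy
#'   (.40,.15,.15,.15,.15) for controls and (.20,.35,.15,.15,.15) for
#'   arthritics at `dwell_scale` 50 frames.
#' @param dwell_scale Mean frames between switch opportunities for the default
#'   transition matrices (default 50, i.e. 20 s at 0.4 s/frame).
#' @param subnetwork_attenuation Factor in \[0, 1\] applied to the shared
#'   carrier amplitude of `attenuated_rois` in arthritic animals at the mean
#'   latent severity; the lost power is replaced by an independent band-limited
#'   private component (default 0.5; 1 disables the effect).
#' @param attenuated_rois ROI labels forming the perturbed sub-network
#'   (default the bilateral S1HL pair).
#' @param severity_range Range of the latent severity, drawn uniformly for
#'   arthritic animals (default c(0.5, 1); controls have severity 0).
#' @param behavior_link Named loadings in \[0, 1\] scaling how strongly each
#'   behavioural variable follows the latent severity (default all 1).
#' @param behavior_noise_scale Multiplier on all behavioural residual SDs
#'   (default 1; 0 makes behaviour a deterministic function of severity).
#' @param ramp Frames over which phase offsets are interpolated at a state
#'   switch (default 2).
#' @param acquisition An [acquisition_geometry()] object (default geometry).
#' @param seed Integer seed consumed by [simulate_cohort()].
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_roi = 10,
                          roi_labels = default_roi_labels(n_roi),
                          n_control = 9,
                          n_arthritic = 9,
                          carrier_freq = 0.08,
                          noise_sd = 0.1,
                          states = default_states(n_roi),
                          transition_control = NULL,
                          transition_arthritic = NULL,
                          dwell_scale = 50,
                          subnetwork_attenuation = 0.5,
                          attenuated_rois = intersect(
                            c("S1HL_L", "S1HL_R"), roi_labels
                          ),
                          severity_range = c(0.5, 1),
                          behavior_link = NULL,
                          behavior_noise_scale = 1,
                          ramp = 2,
                          acquisition = acquisition_geometry(),
                          seed = 1L) {
  if (length(roi_labels) != n_roi || anyDuplicated(roi_labels)) {
    fus_abort("`roi_labels` must be `n_roi` unique labels.")
  }
  if (subnetwork_attenuation < 0 || subnetwork_attenuation > 1) {
    fus_abort("`subnetwork_attenuation` must lie in [0, 1].")
  }
  if (!all(attenuated_rois %in% roi_labels)) {
    fus_abort("`attenuated_rois` must be a subset of `roi_labels`.")
  }
  bad_state <- purrr::detect_index(
    states, function(s) length(s$phase_offsets) != n_roi
  )
  if (bad_state > 0) {
    fus_abort(sprintf("state %d does not have %d phase offsets.", bad_state, n_roi))
  }
  k <- length(states)
  if (is.null(transition_control)) {
    transition_control <- transition_from_occupancy(
      c(0.40, rep(0.60 / (k - 1), k - 1)), dwell_scale
    )
  }
  if (is.null(transition_arthritic)) {
    occ <- c(0.20, 0.35, rep(0.45 / max(k - 2, 1), max(k - 2, 0)))[seq_len(k)]
    transition_arthritic <- transition_from_occupancy(occ / sum(occ), dwell_scale)
  }
  check_transition(transition_control, k)
  check_transition(transition_arthritic, k)
  link_default <- setNames(rep(1, 6), behavior_variables())
  if (!is.null(behavior_link)) {
    if (is.null(names(behavior_link)) ||
        !all(names(behavior_link) %in% behavior_variables())) {
      fus_abort(sprintf(
        "`behavior_link` names must be among: %s.",
        paste(behavior_variables(), collapse = ", ")
      ))
    }
    link_default[names(behavior_link)] <- behavior_link
  }
  structure(
    list(
      n_roi = n_roi, roi_labels = roi_labels,
      n_control = n_control, n_arthritic = n_arthritic,
      carrier_freq = carrier_freq, noise_sd = noise_sd,
      states = states,
      transition_control = transition_control,
      transition_arthritic = transition_arthritic,
      dwell_scale = dwell_scale,
      subnetwork_attenuation = subnetwork_attenuation,
      attenuated_rois = attenuated_rois,
      severity_range = severity_range,
      behavior_link = link_default,
      behavior_noise_scale = behavior_noise_scale,
      ramp = ramp,
      acquisition = acquisition,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

behavior_variables <- function() {
  c("weight_gain", "inflammation_score",
    "vonfrey_left", "vonfrey_right", "bend_left", "bend_right")
}

check_transition <- function(P, k) {
  if (!is.matrix(P) || nrow(P) != k || ncol(P) != k ||
      any(P < -1e-12) || any(abs(rowSums(P) - 1) > 1e-8)) {
    fus_abort("transition matrix must be row-stochastic over the states.",
              class = "fusfc_bad_transition")
  }
  invisible(P)
}
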