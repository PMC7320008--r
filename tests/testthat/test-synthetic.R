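two_state_config <- function(P = matrix(0.5, 2, 2)) {
  cohort_config(
    n_roi = 4, roi_labels = c("A", "B", "C", "D"),
    states = list(
      state_spec(rep(0, 4), "in_phase"),
      state_spec(c(0, pi, pi, pi), "split")
    ),
    transition_control = P, transition_arthritic = P
  )
}

test_that("state sequences follow the transition structure", {
  cfg <- two_state_config(diag(2))
  s <- simulate_state_sequence(cfg, "control", n_frames = 500, init = 2)
  expect_true(all(s == 2L))

  cfg <- two_state_config()
  set.seed(42)
  s <- simulate_state_sequence(cfg, "control", n_frames = 1e5)
  occ <- mean(s == 1)
  expect_lt(abs(occ - 0.5), 3 * sqrt(0.25 / 1e5))
  # occupancy conservation: chi-square goodness of fit to the stationary law
  gof <- stats::chisq.test(tabulate(s, 2), p = c(0.5, 0.5))
  expect_gt(gof$p.value, 1e-3)

  bad <- two_state_config()
  bad$transition_control <- matrix(c(0.7, 0.5, 0.2, 0.5), 2, 2)
  expect_error(simulate_state_sequence(bad, "control"),
               class = "fusfc_bad_transition")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohort_config(n_control = 2, n_arthritic = 2, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$state_seq, c2$state_seq)
  expect_identical(c1$series, c2$series)
  expect_identical(c1$weight_gain, c2$weight_gain)
})

test_that("noise-free single-state signals have the planted correlations", {
  cfg <- two_state_config(diag(2))
  cfg$noise_sd <- 0
  st <- rep(1L, 1500)
  ser <- preprocess(simulate_roi_signals(cfg, st, "control"))
  r <- unclass(correlation_matrix(ser))
  expect_true(all(abs(r - 1) < 1e-9))

  st2 <- rep(2L, 1500) # ROI A in antiphase with B, C, D
  ser2 <- preprocess(simulate_roi_signals(cfg, st2, "control"))
  r2 <- unclass(correlation_matrix(ser2))
  expect_true(all(abs(r2["A", c("B", "C", "D")] + 1) < 1e-6))
  expect_true(all(abs(r2[c("B", "C"), c("C", "D")] - 1) < 1e-9))
})

test_that("invalid carrier frequency and severity are rejected", {
  cfg <- two_state_config()
  cfg$carrier_freq <- 2 # above the 1.25 Hz Nyquist at 0.4 s frames
  expect_error(simulate_roi_signals(cfg, rep(1L, 10), "control"), "Nyquist|carrier")
  cfg2 <- two_state_config()
  expect_error(
    simulate_roi_signals(cfg2, rep(1L, 10), "arthritic", severity = 1.5),
    "severity"
  )
  expect_error(simulate_behavior(cfg2, c(0.2, -0.1), c("control", "control")),
               "severity")
})

test_that("behaviour reproduces the generative group means and bounds", {
  cfg <- cohort_config(seed = 5)
  set.seed(5)
  sev <- runif(200, cfg$severity_range[1], cfg$severity_range[2])
  beh <- simulate_behavior(
    cfg, c(rep(0, 200), sev), rep(c("control", "arthritic"), each = 200)
  )
  ctrl <- beh$group == "control"
  # configured generative means; 3 SEM bands at n = 200
  expect_lt(abs(mean(beh$weight_gain[ctrl]) - 136.00), 3 * 35.28 / sqrt(200))
  expect_lt(abs(mean(beh$weight_gain[!ctrl]) - 49.44), 3 * 35 / sqrt(200))
  expect_equal(median(beh$inflammation_score[ctrl]), 0)
  expect_lt(abs(median(beh$inflammation_score[!ctrl]) - 22), 3)
  expect_true(all(beh$inflammation_score >= 0 & beh$inflammation_score <= 60))
  expect_true(all(beh$bend_left %in% 0:5 & beh$bend_right %in% 0:5))
})

test_that("behaviour loadings control the severity link", {
  cfg <- cohort_config(
    behavior_link = setNames(rep(0, 6), c(
      "weight_gain", "inflammation_score", "vonfrey_left", "vonfrey_right",
      "bend_left", "bend_right"
    )),
    seed = 6
  )
  set.seed(6)
  sev <- runif(500, 0.5, 1)
  beh <- simulate_behavior(cfg, sev, rep("arthritic", 500))
  # zero loading: arthritic behaviour is drawn from the control model
  expect_lt(abs(mean(beh$weight_gain) - 136.00), 3 * 35.28 / sqrt(500))
  expect_lt(abs(cor(beh$weight_gain, sev)), 0.15)

  cfg1 <- cohort_config(behavior_noise_scale = 0, seed = 6)
  beh1 <- simulate_behavior(cfg1, sev, rep("arthritic", 500))
  # noiseless, loading 1: inflammation is a monotone function of severity
  # integer discretization of the score introduces ties, so rho is near 1
  expect_gt(cor(beh1$inflammation_score, sev, method = "spearman"), 0.995)
})

test_that("severity attenuates the shared-carrier weight monotonically", {
  cfg <- single_state_config(noise_sd = 0)
  st <- rep(1L, 1500)
  sevs <- c(0.5, 0.7, 0.9)
  w <- purrr::map_dbl(sevs, function(s) {
    ser <- simulate_roi_signals(cfg, st, "arthritic", severity = s)
    attr(ser, "carrier_weight")[["S1HL_L"]]
  })
  expect_true(all(diff(w) < 0))
  ser0 <- simulate_roi_signals(cfg, st, "control", severity = 0)
  expect_true(all(attr(ser0, "carrier_weight") == 1))
})

test_that("doppler movies copy ROI signals into masks and reject bad masks", {
  cfg <- two_state_config(diag(2))
  cfg$noise_sd <- 0.05
  set.seed(3)
  ser <- simulate_roi_signals(cfg, rep(1L, 300), "control")
  mk <- default_roi_masks(4, n_z = 16, n_x = 24, labels = c("A", "B", "C", "D"))
  set.seed(4)
  mov <- simulate_doppler_movie(ser, mk$roi_masks, mk$brain_mask,
                                pixel_noise_sd = 0)
  px <- which(mk$roi_masks$B, arr.ind = TRUE)[1, ]
  expect_equal(mov$data[px[1], px[2], ], series_matrix(ser)[, "B"])
  extr <- extract_roi_signals(mov)
  expect_equal(series_matrix(extr), series_matrix(ser), tolerance = 1e-12)

  empty <- mk$roi_masks
  empty$A[] <- FALSE
  expect_error(
    simulate_doppler_movie(ser, empty, mk$brain_mask),
    "A", class = "fusfc_empty_mask"
  )
  overlap <- mk$roi_masks
  overlap$A <- overlap$B
  expect_error(
    simulate_doppler_movie(ser, overlap, mk$brain_mask),
    class = "fusfc_overlap_mask"
  )
})
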