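fp <- 0.4
tt <- (0:1499) * fp

sinusoid_series <- function(freqs, phases = rep(0, length(freqs))) {
  x <- sapply(seq_along(freqs), function(j) {
    cos(2 * pi * freqs[j] * tt + phases[j])
  })
  colnames(x) <- paste0("R", seq_along(freqs))
  toy_series(x, fp, preprocessed = TRUE)
}

test_that("instantaneous phase of a cosine advances at the carrier rate", {
  ph <- hilbert_phase(sinusoid_series(c(0.1, 0.1)))
  expect_equal(nrow(ph), 1300)
  expect_equal(attr(ph, "retained"), c(101, 1400))
  d <- diff(ph$R1)
  d <- (d + pi) %% (2 * pi) - pi # wrap increments
  slope <- mean(d) / fp
  expect_lt(abs(slope - 2 * pi * 0.1) / (2 * pi * 0.1), 0.01)

  neg <- sinusoid_series(c(0.1, 0.1), c(0, pi)) # R2 = -R1
  phn <- hilbert_phase(neg)
  dphi <- (phn$R2 - phn$R1) %% (2 * pi)
  expect_lt(max(abs(dphi - pi)), 0.02)

  short <- toy_series(cbind(r = rnorm(150)), fp, preprocessed = TRUE)
  expect_error(hilbert_phase(short), class = "fusfc_too_short")
})

test_that("phase-locking tensors obey their invariants", {
  s <- sinusoid_series(c(0.1, 0.1, 0.1, 0.1), c(0, pi, pi / 2, 0.3))
  pl <- phase_locking(hilbert_phase(s))
  expect_equal(dim(pl), c(4, 4, 1300))
  expect_true(all(abs(pl[cbind(1:4, 1:4, rep(1, 4))] - 1) < 1e-12))
  expect_true(all(pl >= -1 - 1e-12 & pl <= 1 + 1e-12))
  # symmetry at sampled frames
  for (t in c(1, 650, 1300)) {
    expect_equal(pl[, , t], t(pl[, , t]))
  }
  expect_true(all(abs(pl[1, 2, ] + 1) < 0.02))       # antiphase -> -1
  expect_lt(abs(mean(pl[1, 3, ])), 0.02)             # quadrature -> mean 0
})

test_that("pooled features have the right geometry and round-trip", {
  s <- sinusoid_series(rep(0.1, 5), c(0, 0.4, 0.9, 1.4, 2))
  pl1 <- phase_locking(hilbert_phase(s))
  attr(pl1, "animal_id") <- "A01"
  pl2 <- pl1
  attr(pl2, "animal_id") <- "A02"
  pf <- pool_features(list(pl1, pl2))
  expect_equal(dim(pf$features), c(2 * 1300, 5 * 4 / 2))
  expect_equal(nrow(pf$index), 2600)
  expect_equal(unique(pf$index$animal_id), c("A01", "A02"))
  # features of frame t equal the vectorized upper triangle of that frame
  expect_equal(pf$features[7, ], vectorize_pl(pl1[, , 7]))

  m <- unvectorize_pl(pf$features[7, ], dimnames(pl1)[[1]])
  expect_equal(m, pl1[, , 7], tolerance = 1e-12)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 5))
})

test_that("L1 k-means recovers planted well-separated clusters exactly", {
  set.seed(30)
  centers <- matrix(c(0, 0, 0, 6, 6, 0, 6, 6), 4, 2, byrow = TRUE)
  X <- centers[rep(1:4, each = 40), ] + matrix(rnorm(320, 0, 0.3), 160, 2)
  truth <- rep(1:4, each = 40)
  mdl <- kmeans_states(X, 4, n_replicates = 30)
  perms <- fusfc:::injections(4, 4)
  acc <- max(vapply(perms, function(p) mean(p[mdl$labels$state] == truth), 0))
  expect_equal(acc, 1)
  # objective equals recomputed within-cluster L1 distance
  obj <- sum(vapply(seq_len(160), function(i) {
    sum(abs(X[i, ] - mdl$centroid_features[mdl$labels$state[i], ]))
  }, 0))
  expect_equal(mdl$objective, obj, tolerance = 1e-9)
  expect_equal(mdl$objective, min(mdl$replicate_objectives))
})

test_that("k = 1 returns the component-wise median and seeds reproduce", {
  set.seed(31)
  X <- matrix(rnorm(99 * 3), 99, 3)
  mdl <- kmeans_states(X, 1, n_replicates = 3)
  expect_equal(as.numeric(mdl$centroid_features),
               apply(X, 2, median), tolerance = 1e-12)

  same <- matrix(1, 50, 4)
  expect_error(kmeans_states(same, 2), class = "fusfc_k_too_large")
  one <- kmeans_states(same, 1, n_replicates = 2)
  expect_equal(one$objective, 0)

  set.seed(77); m1 <- kmeans_states(X, 3, n_replicates = 10)
  set.seed(77); m2 <- kmeans_states(X, 3, n_replicates = 10)
  expect_identical(m1$labels$state, m2$labels$state)
  expect_identical(m1$centroid_features, m2$centroid_features)
})

test_that("state matching recovers identity and permutations", {
  set.seed(32)
  cf <- matrix(rnorm(5 * 9), 5, 9)
  mk <- function(f) list(centroid_features = f)
  self <- match_states(mk(cf), mk(cf))
  expect_equal(self$state_b, self$state_a)
  expect_equal(self$distance, rep(0, 5))

  perm <- c(3, 1, 5, 2, 4)
  mm <- match_states(mk(cf), mk(cf[perm, ]))
  expect_equal(mm$state_b[order(mm$state_a)], order(perm))
  expect_equal(mm$distance, rep(0, 5))

  # k = 5 vs k = 6 with 5 planted states: surplus state unmatched
  extra <- rbind(cf, rnorm(9) + 10)
  m56 <- match_states(mk(cf), mk(extra))
  expect_equal(nrow(m56), 5)
  expect_equal(attr(m56, "unmatched"), 6L)
  expect_true(all(m56$distance < 1e-12))
})

test_that("occurrence rates sum to one and need both groups", {
  set.seed(33)
  X <- matrix(rnorm(200 * 3), 200, 3)
  X[101:200, ] <- X[101:200, ] + 5
  pf <- structure(
    list(
      features = X,
      index = tibble::tibble(
        animal_id = rep(sprintf("x%02d", 1:8), each = 25),
        group = rep(c("control", "arthritic"), each = 100)[seq(1, 200)],
        cohort = "test",
        frame = rep(1:25, 8)
      ),
      roi_labels = NULL
    ),
    class = "pl_features"
  )
  mdl <- kmeans_states(pf, 2, n_replicates = 10)
  occ <- as.matrix(mdl$occurrence[, c("occ_1", "occ_2")])
  expect_equal(unname(rowSums(occ)), rep(1, 8), tolerance = 1e-9)

  st <- occurrence_group_stats(mdl)
  expect_equal(nrow(st), 2)
  expect_true(all(st$p_raw >= 0 & st$p_raw <= 1))

  bad <- mdl
  bad$occurrence$group <- "control"
  expect_error(occurrence_group_stats(bad), "two groups")
})
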