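# internal: analytic signal via the standard FFT construction
# (double the positive frequencies, zero the negative ones)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every ROI via the Hilbert transform
#'
#' Forms the analytic signal `z(t) = f(t) + iH[f(t)]` of each (band-passed,
#' normalized) ROI signal, takes its phase by the four-quadrant arctangent of
#' the imaginary over the real part, and trims the first and last `trim`
#' samples, where filter and Hilbert edge transients live (1500 frames at
#' 0.4 s become 1300 retained frames, 520 s).
#'
#' @param series A preprocessed [roi_series()].
#' @param trim Samples discarded at each end (default 100).
#' @return A tibble of class `phase_series`: `time` plus one phase column per
#'   ROI (radians, in (-pi, pi\]), with attributes `retained` (frame index
#'   range kept), `frame_period`, `animal_id`, `group`, `cohort`.
#' @export
hilbert_phase <- function(series, trim = 100) {
  stopifnot(inherits(series, "roi_series"))
  if (!isTRUE(attr(series, "preprocessed"))) {
    warn("`series` is not preprocessed; band-pass + normalize first.")
  }
  x <- series_matrix(series)
  n_t <- nrow(x)
  if (n_t <= 2 * trim) {
    fus_abort(sprintf(
      "need more than %d frames to trim %d from each end.", 2 * trim, trim
    ), class = "fusfc_too_short")
  }
  keep <- (trim + 1):(n_t - trim)
  ph <- apply(x, 2, function(v) Arg(analytic_signal(v)))[keep, , drop = FALSE]
  out <- as_tibble(ph)
  out <- dplyr::mutate(out, time = series$time[keep], .before = 1)
  structure(
    out,
    retained = range(keep),
    frame_period = frame_period(series),
    animal_id = attr(series, "animal_id"),
    group = attr(series, "group"),
    cohort = attr(series, "cohort"),
    class = c("phase_series", class(tibble()))
  )
}

#' Per-frame phase-locking tensor
#'
#' `M_PL(i, j, t) = cos(phi_i(t) - phi_j(t))`: a symmetric unit-diagonal
#' matrix per retained frame describing the instantaneous coupling of every
#' ROI pair.
#'
#' @param phases A `phase_series` from [hilbert_phase()].
#' @return An array `n_roi x n_roi x n_t_retained` of class `pl_tensor`, with
#'   ROI labels on the first two dimnames and attributes `animal_id`,
#'   `group`, `cohort`.
#' @export
phase_locking <- function(phases) {
  stopifnot(inherits(phases, "phase_series"))
  ph <- as.matrix(phases[setdiff(names(phases), "time")])
  labs <- colnames(ph)
  n_t <- nrow(ph)
  n_r <- ncol(ph)
  cp <- cos(ph)
  sp <- sin(ph)
  out <- array(NA_real_, c(n_r, n_r, n_t), dimnames = list(labs, labs, NULL))
  for (t in seq_len(n_t)) {
    m <- tcrossprod(cp[t, ]) + tcrossprod(sp[t, ]) # cos(a-b) expansion
    diag(m) <- 1
    out[, , t] <- m
  }
  structure(
    out,
    animal_id = attr(phases, "animal_id"),
    group = attr(phases, "group"),
    cohort = attr(phases, "cohort"),
    class = c("pl_tensor", "array")
  )
}

# internal: strict-upper-triangle pair names "a~b"
pair_names <- function(labs) {
  idx <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste(labs[idx[, 1]], labs[idx[, 2]], sep = "~")
}

#' Vectorize the strict upper triangle of a symmetric matrix
#' @param m Symmetric matrix with ROI dimnames.
#' @return Named numeric vector (`n(n-1)/2` entries, names `roiA~roiB`).
#' @export
vectorize_pl <- function(m) {
  labs <- colnames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  setNames(m[idx], pair_names(labs))
}

#' Rebuild a symmetric unit-diagonal matrix from its vectorized triangle
#' @param v Vector from [vectorize_pl()].
#' @param labs ROI labels.
#' @return Symmetric matrix with unit diagonal.
#' @export
unvectorize_pl <- function(v, labs) {
  n <- length(labs)
  m <- diag(n)
  dimnames(m) <- list(labs, labs)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Pool phase-locking frames of all animals into one feature matrix
#'
#' One row per (animal, retained frame); features are the strict upper
#' triangle of the frame's phase-locking matrix (the diagonal is constant 1
#' and carries no information). 18 animals x 1300 frames x 10 ROIs give a
#' 23400 x 45 matrix.
#'
#' @param tensors List of `pl_tensor` arrays (identical ROI sets).
#' @return A list of class `pl_features`: `features` (matrix), `index`
#'   (tibble animal_id, group, cohort, frame), `roi_labels`.
#' @export
pool_features <- function(tensors) {
  stopifnot(length(tensors) >= 1, all(purrr::map_lgl(tensors, inherits, "pl_tensor")))
  labs <- dimnames(tensors[[1]])[[1]]
  ok <- purrr::map_lgl(tensors, function(a) identical(dimnames(a)[[1]], labs))
  if (!all(ok)) fus_abort("animals have mismatched ROI sets.")
  n_r <- length(labs)
  ut <- which(upper.tri(diag(n_r)))
  ord <- order(row(diag(n_r))[ut], col(diag(n_r))[ut])
  blocks <- purrr::map(tensors, function(a) {
    n_t <- dim(a)[3]
    flat <- matrix(a, n_r * n_r, n_t)
    t(flat[ut[ord], , drop = FALSE])
  })
  idx <- purrr::map(tensors, function(a) {
    tibble(
      animal_id = attr(a, "animal_id") %||% NA_character_,
      group = attr(a, "group") %||% NA_character_,
      cohort = attr(a, "cohort") %||% NA_character_,
      frame = seq_len(dim(a)[3])
    )
  })
  feats <- do.call(rbind, blocks)
  colnames(feats) <- pair_names(labs)
  structure(
    list(features = feats, index = dplyr::bind_rows(idx), roi_labels = labs),
    class = "pl_features"
  )
}

#' Extract brain states by L1 (cityblock) k-means
#'
#' Lloyd-style alternation under the cityblock distance: frames are assigned
#' to their nearest centroid in L1, and each centroid is updated to the
#' component-wise median of its members (the L1-optimal center). The
#' algorithm is restarted from `n_replicates` random initializations (k
#' distinct frames each) and the replicate with the smallest total
#' within-cluster distance is kept. Occurrence rates are the fraction of each
#' animal's frames assigned to each state.
#'
#' @param pooled A `pl_features` object from [pool_features()], or a bare
#'   feature matrix.
#' @param k Number of states (>= 2; k = 1 returns the global median).
#' @param n_replicates Random restarts (default 200).
#' @param max_iter Lloyd iteration cap per replicate (default 300).
#' @return An object of class `brain_state_model`: `k`, `centroids` (list of
#'   symmetric unit-diagonal matrices), `centroid_features`, `labels` (tibble
#'   animal_id, group, cohort, frame, state), `occurrence` (tibble, one row
#'   per animal, `occ_1..occ_k` summing to 1), `objective`,
#'   `replicate_objectives`, `best_replicate`.
#' @export
kmeans_states <- function(pooled, k, n_replicates = 200, max_iter = 300) {
  if (inherits(pooled, "pl_features")) {
    X <- pooled$features
    index <- pooled$index
    labs <- pooled$roi_labels
  } else {
    X <- as.matrix(pooled)
    index <- tibble(
      animal_id = "A01", group = NA_character_, cohort = NA_character_,
      frame = seq_len(nrow(X))
    )
    labs <- NULL
  }
  if (k < 1) fus_abort("`k` must be >= 1.")
  n_distinct_rows <- nrow(unique(X))
  if (k > n_distinct_rows) {
    fus_abort(sprintf(
      "k = %d exceeds the %d distinct frames.", k, n_distinct_rows
    ), class = "fusfc_k_too_large")
  }
  inits <- t(replicate(n_replicates, sample.int(nrow(X), k))) - 1L
  if (k == 1L) inits <- matrix(inits, ncol = 1L)
  fit <- .kmedians_fit(X, inits, as.integer(max_iter))

  cent <- fit$centroids
  colnames(cent) <- colnames(X)
  centroids <- if (!is.null(labs)) {
    purrr::map(seq_len(k), function(c) unvectorize_pl(cent[c, ], labs))
  } else {
    purrr::map(seq_len(k), function(c) cent[c, ])
  }
  labels <- dplyr::mutate(index, state = fit$labels)
  occurrence <- labels |>
    dplyr::count(.data$animal_id, .data$group, .data$cohort, .data$state) |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(occ = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(
      names_from = "state", values_from = "occ",
      names_prefix = "occ_",
      names_sort = TRUE,
      values_fill = 0
    )
  missing_states <- setdiff(paste0("occ_", seq_len(k)), names(occurrence))
  for (ms in missing_states) occurrence[[ms]] <- 0
  occurrence <- occurrence[c(
    "animal_id", "group", "cohort", paste0("occ_", seq_len(k))
  )]
  structure(
    list(
      k = k,
      centroids = centroids,
      centroid_features = cent,
      labels = labels,
      occurrence = occurrence,
      objective = fit$objective,
      replicate_objectives = as.numeric(fit$replicate_objectives),
      best_replicate = fit$best_replicate,
      roi_labels = labs
    ),
    class = "brain_state_model"
  )
}

#' @export
print.brain_state_model <- function(x, ...) {
  cat(sprintf(
    "<brain_state_model> k = %d | %d frames, %d animals | objective %.4g (best of %d replicates)\n",
    x$k, nrow(x$labels), dplyr::n_distinct(x$labels$animal_id),
    x$objective, length(x$replicate_objectives)
  ))
  invisible(x)
}

# internal: all injections of seq_len(ka) into seq_len(kb), ka <= kb
injections <- function(ka, kb) {
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    purrr::flatten(purrr::map(seq_along(v), function(i) {
      purrr::map(perm(v[-i]), function(p) c(v[i], p))
    }))
  }
  if (ka == kb) return(perm(seq_len(kb)))
  combs <- utils::combn(kb, ka, simplify = FALSE)
  purrr::flatten(purrr::map(combs, perm))
}

#' Match the states of two brain-state models
#'
#' Finds the one-to-one assignment (rectangular allowed: every state of the
#' smaller model is matched) minimizing the summed L1 distance between
#' centroid feature vectors, by exhaustive search over assignments (k <= 8).
#'
#' @param model_a,model_b `brain_state_model` objects over the same feature
#'   space.
#' @return A tibble (`state_a`, `state_b`, `distance`), one row per matched
#'   pair, plus attribute `unmatched` listing surplus states of the larger
#'   model.
#' @export
match_states <- function(model_a, model_b) {
  A <- model_a$centroid_features
  B <- model_b$centroid_features
  if (ncol(A) != ncol(B)) fus_abort("models use different feature spaces.")
  swapped <- nrow(A) > nrow(B)
  if (swapped) { tmp <- A; A <- B; B <- tmp }
  ka <- nrow(A); kb <- nrow(B)
  if (kb > 8) fus_abort("exhaustive matching supports k <= 8.")
  D <- matrix(0, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    D[i, j] <- sum(abs(A[i, ] - B[j, ]))
  }
  best <- NULL
  best_cost <- Inf
  for (asg in injections(ka, kb)) {
    cost <- sum(D[cbind(seq_len(ka), asg)])
    if (cost < best_cost) { best_cost <- cost; best <- asg }
  }
  out <- tibble(
    state_a = if (swapped) best else seq_len(ka),
    state_b = if (swapped) seq_len(ka) else best,
    distance = D[cbind(seq_len(ka), best)]
  )
  structure(out, unmatched = setdiff(seq_len(kb), best), total = best_cost)
}

#' Group comparison of state occurrence rates
#'
#' Per state: normality-gated Welch / Mann-Whitney comparison of the
#' per-animal occurrence rates between groups, Benjamini-Hochberg corrected
#' across the k states.
#'
#' @param model A `brain_state_model`.
#' @param groups Optional tibble (animal_id, group) overriding the group
#'   labels stored in the model.
#' @param fdr False-discovery rate (default 0.05).
#' @return A tibble, one row per state: `state`, `test_used`, `p_raw`,
#'   `p_adj`, `significant`, per-group mean and median occurrence.
#' @export
occurrence_group_stats <- function(model, groups = NULL, fdr = 0.05) {
  occ <- model$occurrence
  if (!is.null(groups)) {
    occ <- dplyr::left_join(
      dplyr::select(occ, -"group"), groups, by = "animal_id"
    )
  }
  if (any(is.na(occ$group))) fus_abort("every animal needs a group label.")
  tab <- table(occ$group)
  if (length(tab) != 2 || any(tab < 3)) {
    fus_abort("need two groups with at least 3 animals each.")
  }
  ctrl <- occ$group == "control"
  rows <- purrr::map(seq_len(model$k), function(s) {
    v <- occ[[paste0("occ_", s)]]
    cmp <- group_compare(v[ctrl], v[!ctrl])
    tibble(
      state = s, test_used = cmp$test_used, p_raw = cmp$p_raw,
      mean_occ_control = mean(v[ctrl]),
      mean_occ_arthritic = mean(v[!ctrl]),
      median_occ_control = median(v[ctrl]),
      median_occ_arthritic = median(v[!ctrl])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$significant <- bh_correct(out$p_raw, fdr)
  dplyr::relocate(out, "p_adj", "significant", .after = "p_raw")
}

#' Fit brain states straight from a cohort
#'
#' Convenience wrapper: preprocess every animal, extract phases, build
#' phase-locking tensors, pool, and cluster at each requested k.
#'
#' @param cohort A `fus_cohort` (or tibble with a `series` list-column).
#' @param k_list Numbers of states to fit (default 5:7, fit independently).
#' @param n_replicates,max_iter Passed to [kmeans_states()].
#' @param trim Samples trimmed at each end by [hilbert_phase()].
#' @return A named list of `brain_state_model`s (names `"k5"`, ...); a single
#'   model if `k_list` has length 1.
#' @export
brain_states <- function(cohort, k_list = c(5, 6, 7), n_replicates = 200,
                         max_iter = 300, trim = 100) {
  tensors <- purrr::map(cohort$series, function(s) {
    phase_locking(hilbert_phase(preprocess(s), trim = trim))
  })
  pooled <- pool_features(tensors)
  models <- purrr::map(k_list, function(k) {
    kmeans_states(pooled, k, n_replicates = n_replicates, max_iter = max_iter)
  })
  if (length(models) == 1L) models[[1]] else
    setNames(models, paste0("k", k_list))
}
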