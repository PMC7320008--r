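# Shared fixtures and small oracles, all built in code.

# a cheap single-state config for static-connectivity tests
single_state_config <- function(..., n_roi = 10) {
  one <- list(state_spec(rep(0, n_roi), label = "in_phase"))
  cohort_config(
    n_roi = n_roi,
    states = one,
    transition_control = matrix(1, 1, 1),
    transition_arthritic = matrix(1, 1, 1),
    ...
  )
}

# tiny raw series with known content
toy_series <- function(x, frame_period = 0.4, preprocessed = FALSE) {
  roi_series(x, frame_period = frame_period, preprocessed = preprocessed)
}

# planted centroid feature matrix for a list of state_spec offsets
planted_centroid_features <- function(states, labs) {
  feats <- t(vapply(states, function(s) {
    m <- cos(outer(s$phase_offsets, s$phase_offsets, "-"))
    dimnames(m) <- list(labs, labs)
    vectorize_pl(m)
  }, numeric(length(labs) * (length(labs) - 1) / 2)))
  feats
}

# map recovered state labels onto planted states via centroid matching,
# then score frame agreement
matched_frame_accuracy <- function(model, states, truth) {
  planted <- list(centroid_features = planted_centroid_features(
    states, model$roi_labels
  ))
  mm <- match_states(model, planted)
  map <- integer(model$k)
  map[mm$state_a] <- mm$state_b
  mean(map[model$labels$state] == truth)
}

# retained planted labels for a cohort (default 100-frame trim)
retained_truth <- function(cohort, trim = 100) {
  unlist(purrr::map(cohort$state_seq, function(st) {
    st[(trim + 1):(length(st) - trim)]
  }))
}

# brute-force AUC: exhaustive pair counting with half ties
auc_bruteforce <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# hand step-up BH oracle
bh_stepup <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}
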