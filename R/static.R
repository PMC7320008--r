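#' Pearson correlation between two ROI signals
#'
#' @param series A preprocessed [roi_series()].
#' @param roi_a,roi_b ROI labels.
#' @return Pearson r.
#' @export
roi_pair_r <- function(series, roi_a, roi_b) {
  x <- series_matrix(series)
  for (lab in c(roi_a, roi_b)) {
    if (!lab %in% colnames(x)) fus_abort(sprintf("unknown ROI '%s'.", lab))
    if (stats::sd(x[, lab]) == 0) {
      fus_abort(sprintf("ROI '%s' is constant; r is undefined.", lab),
                class = "fusfc_constant_signal")
    }
  }
  stats::cor(x[, roi_a], x[, roi_b])
}

#' ROI-ROI Pearson correlation matrix
#'
#' @inheritParams roi_pair_r
#' @return A symmetric unit-diagonal matrix of class `fus_cormat`.
#' @export
correlation_matrix <- function(series) {
  x <- series_matrix(series)
  if (ncol(x) < 2) fus_abort("need at least 2 ROIs.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    fus_abort(sprintf(
      "constant ROI(s): %s.", paste(colnames(x)[sds == 0], collapse = ", ")
    ), class = "fusfc_constant_signal")
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("fus_cormat", "matrix", "array"))
}

#' Per-animal correlation matrices of a cohort
#'
#' Preprocesses (band-pass + energy normalization) each animal's ROI series
#' and computes its correlation matrix.
#'
#' @param cohort A `fus_cohort` from [simulate_cohort()], or any tibble with
#'   `animal_id`, `group`, `cohort` and a `series` list-column.
#' @inheritParams bandpass
#' @return Tibble (animal_id, group, cohort, cormat list-column).
#' @export
fc_matrices <- function(cohort, f_lo = 0.05, f_hi = 0.2, order = 4) {
  mats <- purrr::map(
    cohort$series,
    function(s) correlation_matrix(preprocess(s, f_lo, f_hi, order))
  )
  tibble(
    animal_id = cohort$animal_id,
    group = cohort$group,
    cohort = cohort$cohort,
    cormat = mats
  )
}

#' Seed-based pixelwise correlation map
#'
#' Pearson correlation between the mean signal of a seed ROI and every brain
#' pixel of a band-passed movie. Constant pixels get r = 0 and are reported in
#' the `flagged` attribute (excluded from any statistics) so maps stay
#' renderable.
#'
#' @param movie A band-passed `fus_movie` (see [bandpass_movie()]).
#' @param seed_mask Logical matrix selecting the seed ROI.
#' @param seed_label Label recorded on the map.
#' @return A matrix of class `fus_seedmap` (NA outside the brain) with
#'   attributes `seed_label` and `flagged`.
#' @export
seed_map <- function(movie, seed_mask, seed_label = "seed") {
  stopifnot(inherits(movie, "fus_movie"))
  if (!isTRUE(attr(movie, "preprocessed"))) {
    warn("`movie` is not band-passed; call bandpass_movie() first.")
  }
  if (!any(seed_mask)) {
    fus_abort("seed mask covers zero pixels.", class = "fusfc_empty_mask")
  }
  nz <- dim(movie$data)[1]; nx <- dim(movie$data)[2]
  nt <- dim(movie$data)[3]
  flat <- matrix(movie$data, nz * nx, nt)
  seed_sig <- colMeans(flat[which(seed_mask), , drop = FALSE])
  vals <- matrix(NA_real_, nz, nx)
  flagged <- matrix(FALSE, nz, nx)
  px <- which(movie$brain_mask)
  sds <- apply(flat[px, , drop = FALSE], 1, stats::sd)
  const <- sds == 0
  ok <- px[!const]
  vals[ok] <- as.vector(stats::cor(t(flat[ok, , drop = FALSE]), seed_sig))
  vals[px[const]] <- 0
  flagged[px[const]] <- TRUE
  structure(vals, seed_label = seed_label, flagged = flagged,
            class = c("fus_seedmap", "matrix", "array"))
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = atanh(r)`; variance-stabilizing for group statistics on correlations.
#'
#' @param r Correlations with |r| < 1 (clip explicitly with `clip` if needed).
#' @param clip Optional bound, e.g. `1 - 1e-7`, applied as
#'   `pmin(pmax(r, -clip), clip)` before the transform.
#' @return z values.
#' @export
fisher_z <- function(r, clip = NULL) {
  if (!is.null(clip)) r <- pmin(pmax(r, -clip), clip)
  if (any(abs(r) >= 1)) {
    fus_abort("|r| >= 1; pass `clip` to clip explicitly.",
              class = "fusfc_r_out_of_range")
  }
  atanh(r)
}

#' Normality-gated two-sample group comparison
#'
#' Shapiro-Wilk at `normality_alpha` on each group; if both pass, a two-sided
#' Welch unequal-variance t test, otherwise a two-sided Mann-Whitney U test
#' (exact when both groups have at most `exact_max` observations and no ties,
#' normal approximation with tie correction otherwise).
#'
#' @param values_control,values_arthritic Numeric vectors (>= 3 each).
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @param exact_max Largest per-group n for the exact U distribution
#'   (default 12).
#' @param test `"auto"` (the normality gate, default) or a forced branch
#'   (`"welch"` / `"mann_whitney"`, e.g. for analyses that prescribe the
#'   U test throughout).
#' @return List with `test_used` (`"welch"` or `"mann_whitney"`) and `p_raw`.
#' @export
group_compare <- function(values_control, values_arthritic,
                          normality_alpha = 0.05, exact_max = 12,
                          test = c("auto", "welch", "mann_whitney")) {
  test <- match.arg(test)
  x <- values_control; y <- values_arthritic
  if (length(x) < 3 || length(y) < 3) {
    fus_abort("need at least 3 values per group.")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(list(test_used = "mann_whitney", p_raw = 1))
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    p <- tryCatch(shapiro.test(v)$p.value, error = function(e) 0)
    p > normality_alpha
  }
  use_welch <- switch(test,
    auto = normal(x) && normal(y),
    welch = TRUE,
    mann_whitney = FALSE
  )
  if (use_welch) {
    list(test_used = "welch",
         p_raw = t.test(x, y, var.equal = FALSE)$p.value)
  } else {
    exact <- length(x) <= exact_max && length(y) <= exact_max
    p <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
    )
    list(test_used = "mann_whitney", p_raw = p)
  }
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up procedure at false-discovery rate `fdr`: sort p ascending, find the
#' largest k with `p_(k) <= k * fdr / m`, flag everything at or below `p_(k)`.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param fdr Target false-discovery rate (default 0.05).
#' @return Logical flags, same order as the input.
#' @export
bh_correct <- function(p_values, fdr = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    fus_abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH") <= fdr
}

#' Group-difference significance table over ROI pairs
#'
#' For every unordered ROI pair: Fisher-z each animal's correlation, run the
#' normality-gated group comparison, and apply Benjamini-Hochberg correction
#' across all pairs of the plane.
#'
#' @param fc Output of [fc_matrices()] (per-animal correlation matrices with
#'   group labels); both groups must be present.
#' @param fdr False-discovery rate (default 0.05).
#' @param clip Clip bound applied to r before the Fisher transform.
#' @param group_levels Two group labels, reference first.
#' @return A tibble (one row per pair): `roi_a`, `roi_b`, `test_used`,
#'   `p_raw`, `p_adj`, `significant`, per-group mean and median Fisher z.
#' @export
significance_matrix <- function(fc, fdr = 0.05, clip = 1 - 1e-7,
                                group_levels = c("control", "arthritic")) {
  if (!all(group_levels %in% fc$group)) {
    fus_abort("both groups must be present in `fc`.")
  }
  labs <- colnames(fc$cormat[[1]])
  same <- purrr::map_lgl(fc$cormat, function(m) identical(colnames(m), labs))
  if (!all(same)) fus_abort("animals have mismatched ROI sets.")
  pairs <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  ctrl <- fc$group == group_levels[1]
  rows <- purrr::map(seq_len(nrow(pairs)), function(q) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    z <- fisher_z(purrr::map_dbl(fc$cormat, function(m) m[i, j]), clip = clip)
    cmp <- group_compare(z[ctrl], z[!ctrl])
    tibble(
      roi_a = labs[i], roi_b = labs[j],
      test_used = cmp$test_used, p_raw = cmp$p_raw,
      mean_z_control = mean(z[ctrl]),
      mean_z_arthritic = mean(z[!ctrl]),
      median_z_control = median(z[ctrl]),
      median_z_arthritic = median(z[!ctrl])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  out$significant <- bh_correct(out$p_raw, fdr)
  dplyr::relocate(out, "p_adj", "significant", .after = "p_raw")
}
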