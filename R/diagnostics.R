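#' Composite FC biomarker score per animal
#'
#' Combines the Pearson correlations of an ordered set of ROI pairs into one
#' score per animal. `sum` mode adds the raw correlations (the scale on which
#' a multi-pair correlation threshold lives); `logistic` mode fits a
#' maximum-likelihood logistic regression of group on the pair correlations
#' and returns the linear predictor. The model is fit on the animals of
#' `fit_cohort` only and then applied to every animal, so validation scores
#' never refit. Complete separation (expected at these sample sizes) is
#' caught and refit with a small ridge penalty, which preserves the score
#' ordering that the ROC needs; the result is flagged.
#'
#' @param dataset A tibble from [assemble_dataset()] containing the pair
#'   columns.
#' @param pairs Ordered character vector of pair columns to use.
#' @param mode `"sum"` or `"logistic"`.
#' @param fit_cohort Cohort label(s) used for fitting in logistic mode
#'   (default `"test"`; ignored when the dataset has no `cohort` column).
#' @param positive Group treated as the positive class (default
#'   `"arthritic"`).
#' @return Tibble (`animal_id`, `group`, `cohort`, `score`) with attributes
#'   `mode`, `coefficients` (logistic mode) and `ridged` (logical).
#' @export
composite_score <- function(dataset, pairs, mode = c("sum", "logistic"),
                            fit_cohort = "test", positive = "arthritic") {
  mode <- match.arg(mode)
  miss <- setdiff(pairs, names(dataset))
  if (length(miss)) {
    fus_abort(sprintf("pair column(s) missing: %s.",
                      paste(miss, collapse = ", ")))
  }
  X <- as.matrix(dataset[pairs])
  out <- dplyr::select(
    dataset, "animal_id", "group", dplyr::any_of("cohort")
  )
  if (!"cohort" %in% names(out)) out$cohort <- "test"
  ridged <- FALSE
  coefs <- NULL
  if (mode == "sum") {
    out$score <- rowSums(X)
  } else {
    fit_rows <- out$cohort %in% fit_cohort
    if (!any(fit_rows)) fus_abort("no animals in `fit_cohort`.")
    Xf <- X[fit_rows, , drop = FALSE]
    if (any(apply(Xf, 2, stats::sd) == 0)) {
      fus_abort("constant predictor in the fitting cohort.",
                class = "fusfc_constant_predictor")
    }
    yf <- as.integer(out$group[fit_rows] == positive)
    if (length(unique(yf)) < 2) fus_abort("fitting cohort needs both groups.")
    df <- data.frame(y = yf, Xf)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    probs <- fit$fitted.values
    separated <- !fit$converged || any(probs > 1 - 1e-8) || any(probs < 1e-8)
    if (separated) {
      warn("complete separation in logistic fit; using a ridge-stabilized fit.")
      ridged <- TRUE
      Xr <- if (ncol(Xf) == 1) cbind(Xf, 0) else Xf # glmnet needs >= 2 cols
      gfit <- suppressWarnings(glmnet::glmnet(
        Xr, yf, family = "binomial", alpha = 0, lambda = 1e-4,
        standardize = FALSE
      ))
      coefs <- c(
        as.numeric(gfit$a0),
        as.numeric(gfit$beta[seq_len(ncol(Xf)), 1])
      )
    } else {
      coefs <- as.numeric(stats::coef(fit))
    }
    names(coefs) <- c("(Intercept)", pairs)
    out$score <- as.numeric(coefs[1] + X %*% coefs[-1])
  }
  structure(out, mode = mode, coefficients = coefs, ridged = ridged,
            pairs = pairs, positive = positive)
}

# internal: confusion-derived operating statistics
operating_stats <- function(tp, fp, tn, fn) {
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# internal: DeLong variance of the empirical AUC
delong_se <- function(pos, neg) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- purrr::map_dbl(pos, function(x) mean(psi(x, neg)))
  v01 <- purrr::map_dbl(neg, function(y) mean(psi(pos, y)))
  s10 <- if (length(pos) > 1) stats::var(v10) else 0
  s01 <- if (length(neg) > 1) stats::var(v01) else 0
  sqrt(s10 / length(pos) + s01 / length(neg))
}

#' Empirical ROC curve, AUC and DeLong confidence interval
#'
#' Sweeps the empirical thresholds (midpoints between consecutive observed
#' scores, plus the two extremes), computing sensitivity and 1 -
#' specificity; the AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney U statistic (ties counted one half). The score orientation is
#' auto-detected: if the positive class scores lower on average (a biomarker
#' *reduced* in arthritic animals), the internal oriented score is the
#' negated raw score, and positives are called where the raw score is at or
#' below threshold. The 95% CI is DeLong's.
#'
#' @param scores Tibble from [composite_score()] or a numeric vector.
#' @param labels Group labels (taken from `scores$group` when omitted).
#' @param positive Positive-class label (default `"arthritic"`).
#' @param conf_level CI level (default 0.95).
#' @return An object of class `fus_roc`: list with `points` (threshold, fpr,
#'   tpr on the raw-score scale), `auc`, `auc_ci`, `auc_se`, `direction`
#'   (`">="` when higher raw scores are positive, `"<="` otherwise), `scores`
#'   table, `positive`.
#' @export
roc_curve <- function(scores, labels = NULL, positive = "arthritic",
                      conf_level = 0.95) {
  if (is.data.frame(scores)) {
    labels <- labels %||% scores$group
    tbl <- scores
    s <- scores$score
  } else {
    s <- as.numeric(scores)
    tbl <- tibble(
      animal_id = as.character(seq_along(s)),
      group = labels, cohort = NA_character_, score = s
    )
  }
  if (is.null(labels)) fus_abort("`labels` must be supplied.")
  y <- labels == positive
  if (!any(y) || all(y)) {
    fus_abort("both classes must be present.", class = "fusfc_one_class")
  }
  direction <- if (mean(s[y]) >= mean(s[!y])) ">=" else "<="
  so <- if (direction == ">=") s else -s
  u <- sort(unique(so), decreasing = TRUE)
  # candidate cuts at midpoints between consecutive observed scores, so a
  # frozen threshold sits centrally in its empirical equivalence interval
  thr_o <- if (length(u) > 1) {
    c((head(u, -1) + tail(u, -1)) / 2, -Inf)
  } else {
    -Inf
  }
  pts <- purrr::map(c(Inf, thr_o), function(th) {
    pred <- so >= th
    tibble(
      threshold_oriented = th,
      tpr = sum(pred & y) / sum(y),
      fpr = sum(pred & !y) / sum(!y)
    )
  })
  pts <- dplyr::bind_rows(pts)
  pts$threshold <- if (direction == ">=") pts$threshold_oriented else
    -pts$threshold_oriented
  # trapezoid over the (fpr, tpr) staircase = U/(n+ n-) with half ties
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  se <- delong_se(so[y], so[!y])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  structure(
    list(
      points = dplyr::select(pts, "threshold", "fpr", "tpr"),
      auc = auc, auc_se = se, auc_ci = ci, conf_level = conf_level,
      direction = direction, positive = positive, scores = tbl
    ),
    class = "fus_roc"
  )
}

#' @export
print.fus_roc <- function(x, ...) {
  cat(sprintf(
    "<fus_roc> AUC %.3f (%g%% CI %.3f-%.3f) | positive = '%s' called where score %s threshold\n",
    x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2], x$positive,
    x$direction
  ))
  invisible(x)
}

#' Select an operating threshold on a ROC curve
#'
#' Youden rule: maximize sensitivity + specificity - 1 over the empirical
#' thresholds, breaking ties toward higher sensitivity. Operating statistics
#' are computed on the fitting cohort at the chosen threshold with the
#' convention that an oriented score at or above the threshold is called
#' positive.
#'
#' @param roc A `fus_roc` from [roc_curve()].
#' @param rule Only `"youden"` is implemented.
#' @return The `fus_roc` with added `chosen_threshold` and `operating`
#'   (tibble: tp, fp, tn, fn, sensitivity, specificity, ppv, npv).
#' @export
select_threshold <- function(roc, rule = "youden") {
  stopifnot(inherits(roc, "fus_roc"), rule == "youden")
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  youden <- pts$tpr - pts$fpr
  best <- which(youden == max(youden))
  best <- best[which.max(pts$tpr[best])] # ties -> higher sensitivity
  thr <- pts$threshold[best]
  roc$chosen_threshold <- thr
  roc$operating <- threshold_stats(
    roc$scores$score, roc$scores$group, thr, roc$direction, roc$positive
  )
  roc
}

# internal: confusion at a threshold under the stored direction
threshold_stats <- function(s, labels, threshold, direction, positive) {
  y <- labels == positive
  pred <- if (direction == ">=") s >= threshold else s <= threshold
  operating_stats(
    tp = sum(pred & y), fp = sum(pred & !y),
    tn = sum(!pred & !y), fn = sum(!pred & y)
  )
}

#' Frozen-threshold external validation
#'
#' Applies a threshold (and, in logistic mode, the frozen coefficients
#' already baked into the scores) chosen on the test cohort to a disjoint
#' validation cohort. Nothing is refit; the animals of the two cohorts must
#' not overlap.
#'
#' @param roc A `fus_roc` with a `chosen_threshold` (see
#'   [select_threshold()]), fit on the test cohort.
#' @param validation_scores Tibble (`animal_id`, `group`, `score`) of
#'   validation animals, scored with the frozen model (e.g. the
#'   validation-cohort rows of [composite_score()] output).
#' @return Tibble of operating statistics on the validation animals.
#' @export
external_validate <- function(roc, validation_scores) {
  stopifnot(inherits(roc, "fus_roc"))
  if (is.null(roc$chosen_threshold)) {
    fus_abort("run select_threshold() on the test-cohort ROC first.")
  }
  overlap <- intersect(roc$scores$animal_id, validation_scores$animal_id)
  if (length(overlap)) {
    fus_abort(sprintf(
      "validation cohort overlaps the test cohort: %s.",
      paste(overlap, collapse = ", ")
    ), class = "fusfc_cohort_overlap")
  }
  threshold_stats(
    validation_scores$score, validation_scores$group,
    roc$chosen_threshold, roc$direction, roc$positive
  )
}
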