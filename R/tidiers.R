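#' Tidy a correlation matrix into long format
#' @param x A `fus_cormat`.
#' @param ... Unused.
#' @return Tibble (`roi_a`, `roi_b`, `r`), strict upper triangle.
#' @export
tidy.fus_cormat <- function(x, ...) {
  labs <- colnames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble(
    roi_a = labs[idx[, 1]],
    roi_b = labs[idx[, 2]],
    r = x[idx]
  )
}

#' Tidy a brain-state model into per-animal occurrence rates
#' @param x A `brain_state_model`.
#' @param ... Unused.
#' @return Long tibble (`animal_id`, `group`, `cohort`, `state`,
#'   `occurrence`).
#' @export
tidy.brain_state_model <- function(x, ...) {
  tidyr::pivot_longer(
    x$occurrence,
    dplyr::starts_with("occ_"),
    names_to = "state", names_prefix = "occ_",
    names_transform = as.integer,
    values_to = "occurrence"
  )
}

#' One-row summary of a brain-state model
#' @inheritParams tidy.brain_state_model
#' @return Tibble with `k`, `objective`, `n_frames`, `n_animals`,
#'   `best_replicate`, `n_replicates`.
#' @export
glance.brain_state_model <- function(x, ...) {
  tibble(
    k = x$k,
    objective = x$objective,
    n_frames = nrow(x$labels),
    n_animals = dplyr::n_distinct(x$labels$animal_id),
    best_replicate = x$best_replicate,
    n_replicates = length(x$replicate_objectives)
  )
}

#' Tidy a ROC curve into its operating points
#' @param x A `fus_roc`.
#' @param ... Unused.
#' @return Tibble (`threshold`, `fpr`, `tpr`).
#' @export
tidy.fus_roc <- function(x, ...) x$points

#' One-row summary of a ROC analysis
#' @inheritParams tidy.fus_roc
#' @return Tibble with `auc`, CI bounds, direction and, if a threshold was
#'   selected, the operating statistics.
#' @export
glance.fus_roc <- function(x, ...) {
  out <- tibble(
    auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
    auc_se = x$auc_se, direction = x$direction
  )
  if (!is.null(x$chosen_threshold)) {
    out$chosen_threshold <- x$chosen_threshold
    out <- dplyr::bind_cols(
      out, dplyr::select(x$operating, "sensitivity":"npv")
    )
  }
  out
}

#' Tidy a Spearman block matrix into long format
#' @param x A `spearman_blocks`.
#' @param ... Unused.
#' @return Tibble (`var_a`, `var_b`, `rho`, `p`, `significant`, `block`).
#' @export
tidy.spearman_blocks <- function(x, ...) {
  vars <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  va <- vars[idx[, 1]]
  vb <- vars[idx[, 2]]
  tibble(
    var_a = va, var_b = vb,
    rho = x$rho[idx], p = x$p[idx],
    significant = x$significant[idx],
    block = paste(
      pmin(x$blocks[va], x$blocks[vb]),
      pmax(x$blocks[va], x$blocks[vb]),
      sep = "-"
    )
  )
}

#' Heatmap of an ROI-ROI correlation matrix
#' @param object A `fus_cormat`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fus_cormat <- function(object, ...) {
  labs <- colnames(object)
  df <- as_tibble(as.table(unclass(object)), .name_repair = function(x) {
    c("roi_a", "roi_b", "r")
  })
  df$roi_a <- factor(df$roi_a, levels = labs)
  df$roi_b <- factor(df$roi_b, levels = rev(labs))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_a, .data$roi_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Centroid heatmaps of a brain-state model
#' @param object A `brain_state_model` fit on labelled features.
#' @param ... Unused.
#' @return A ggplot, one facet per state.
#' @export
autoplot.brain_state_model <- function(object, ...) {
  labs <- object$roi_labels
  if (is.null(labs)) fus_abort("model has no ROI labels to plot.")
  df <- purrr::imap(object$centroids, function(m, s) {
    d <- as_tibble(as.table(unclass(m)), .name_repair = function(x) {
      c("roi_a", "roi_b", "value")
    })
    d$state <- paste("state", s)
    d
  })
  df <- dplyr::bind_rows(df)
  df$roi_a <- factor(df$roi_a, levels = labs)
  df$roi_b <- factor(df$roi_b, levels = rev(labs))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi_a, .data$roi_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cos
phase diff") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, size = 6),
      axis.text.y = ggplot2::element_text(size = 6)
    )
}

#' ROC curve plot
#' @param object A `fus_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fus_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("AUC = %.3f (%g%% CI %.3f-%.3f)", object$auc,
                      100 * object$conf_level, object$auc_ci[1],
                      object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Per-group state occurrence plot
#' @param model A `brain_state_model`.
#' @return A ggplot of per-animal occurrence rates by state and group.
#' @export
plot_occurrence <- function(model) {
  df <- tidy(model)
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$state), .data$occurrence, colour = .data$group
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.7)) +
    ggplot2::geom_point(
      position = ggplot2::position_jitterdodge(
        jitter.width = 0.1, dodge.width = 0.7
      ),
      alpha = 0.7
    ) +
    ggplot2::labs(x = "brain state", y = "occurrence rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
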