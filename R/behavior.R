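#' Assemble the per-animal dataset linking FC, states and behaviour
#'
#' Column-aligns, per animal: the Pearson correlations of selected ROI pairs
#' (from the per-animal correlation matrices), the state occurrence rates of
#' a fitted brain-state model, and the behavioural variables.
#'
#' @param fc Output of [fc_matrices()] (may be `NULL` to skip FC columns).
#' @param model A `brain_state_model` (or `NULL` to skip occurrence columns).
#' @param behavior Behaviour tibble with `animal_id` plus measure columns
#'   (or `NULL`).
#' @param pairs Character vector of pair names `"roiA~roiB"` selecting the FC
#'   columns (default: none).
#' @return A `CohortDataset` tibble: `animal_id`, `group`, `cohort`, one
#'   column per selected pair, `occ_*` columns, behaviour columns.
#' @export
assemble_dataset <- function(fc = NULL, model = NULL, behavior = NULL,
                             pairs = character()) {
  blocks <- list()
  base <- NULL
  if (!is.null(fc)) {
    if (anyDuplicated(fc$animal_id)) fus_abort("duplicate animal ids in `fc`.")
    base <- dplyr::select(fc, "animal_id", "group", "cohort")
    if (length(pairs)) {
      labs <- colnames(fc$cormat[[1]])
      vals <- purrr::map(fc$cormat, function(m) {
        v <- vectorize_pl(m)
        miss <- setdiff(pairs, names(v))
        if (length(miss)) {
          fus_abort(sprintf(
            "unknown pair(s): %s.", paste(miss, collapse = ", ")
          ))
        }
        v[pairs]
      })
      fc_tbl <- as_tibble(do.call(rbind, vals))
      fc_tbl$animal_id <- fc$animal_id
      blocks <- c(blocks, list(fc_tbl))
    }
  }
  if (!is.null(model)) {
    occ <- dplyr::select(model$occurrence, -dplyr::any_of(c("group", "cohort")))
    if (is.null(base)) {
      base <- dplyr::select(
        model$occurrence, "animal_id",
        dplyr::any_of(c("group", "cohort"))
      )
    }
    blocks <- c(blocks, list(occ))
  }
  if (!is.null(behavior)) {
    if (anyDuplicated(behavior$animal_id)) {
      fus_abort("duplicate animal ids in `behavior`.")
    }
    beh <- dplyr::select(
      behavior, "animal_id",
      -dplyr::any_of(c("group", "cohort")), dplyr::everything()
    )
    beh <- dplyr::select(beh, -dplyr::any_of(c("group", "cohort")))
    if (is.null(base)) {
      base <- dplyr::select(
        behavior, "animal_id", dplyr::any_of(c("group", "cohort"))
      )
    }
    blocks <- c(blocks, list(beh))
  }
  if (is.null(base)) fus_abort("at least one source must be provided.")
  out <- base
  for (b in blocks) {
    miss <- setdiff(out$animal_id, b$animal_id)
    extra <- setdiff(b$animal_id, out$animal_id)
    if (length(miss) || length(extra)) {
      fus_abort(sprintf(
        "animal mismatch across sources (missing: %s; extra: %s).",
        paste(miss, collapse = ", ") %||% "-",
        paste(extra, collapse = ", ") %||% "-"
      ), class = "fusfc_animal_mismatch")
    }
    out <- dplyr::left_join(out, b, by = "animal_id")
  }
  if (anyNA(out)) fus_abort("assembled dataset contains missing cells.")
  out
}

# internal: Spearman rho via midranks + Pearson, with two-sided p by the
# t approximation or by permutation of one variable
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000) {
  method <- match.arg(method)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    return(list(rho = rho, p = 2 * pt(-abs(tt), df = n - 2)))
  }
  rx <- rank(x)
  ry <- rank(y)
  if (n <= 8) {
    perms <- injections(n, n) # all n! permutations
    stats <- purrr::map_dbl(perms, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(stats) >= abs(rho) - 1e-12)
  } else {
    stats <- purrr::map_dbl(seq_len(n_perm), function(i) {
      stats::cor(rx, sample(ry))
    })
    p <- (1 + sum(abs(stats) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  list(rho = rho, p = p)
}

#' Three-block Spearman correlation matrix of FC and behaviour
#'
#' Pairwise Spearman correlations (tie-corrected midranks) between every pair
#' of selected variables across animals, with Benjamini-Hochberg correction
#' over all unique off-diagonal pairs. Variables are partitioned into an FC
#' block (ROI-pair correlations and state occurrences) and a behaviour block,
#' and each variable pair is labelled `fc-fc`, `fc-behavior` or
#' `behavior-behavior`.
#'
#' @param dataset A tibble from [assemble_dataset()].
#' @param alpha Significance level after correction (default 0.05).
#' @param correction `"bh"` (default) or `"none"`.
#' @param method P-value method per correlation: `"t"` approximation
#'   (default) or `"permutation"` (exhaustive for n <= 8, Monte Carlo
#'   otherwise).
#' @param behavior_vars Names of the behaviour-block columns (default: the
#'   standard six behavioural variables present in the dataset).
#' @return An object of class `spearman_blocks`: list with `rho`, `p`,
#'   `significant` matrices, `blocks` (named character of block membership),
#'   `dropped` (constant columns excluded), `alpha`.
#' @export
spearman_blocks <- function(dataset, alpha = 0.05,
                            correction = c("bh", "none"),
                            method = c("t", "permutation"),
                            behavior_vars = intersect(
                              behavior_variables(), names(dataset)
                            )) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  meta <- intersect(c("animal_id", "group", "cohort"), names(dataset))
  vars <- setdiff(names(dataset), meta)
  num <- purrr::map_lgl(dataset[vars], is.numeric)
  vars <- vars[num]
  if (nrow(dataset) < 5) fus_abort("need at least 5 animals.")
  const <- purrr::map_lgl(dataset[vars], function(v) stats::sd(v) == 0)
  dropped <- vars[const]
  if (length(dropped)) {
    warn(sprintf(
      "constant column(s) excluded: %s.", paste(dropped, collapse = ", ")
    ))
    vars <- vars[!const]
  }
  m <- length(vars)
  if (m < 2) fus_abort("need at least 2 non-constant variables.")
  rho <- diag(m)
  p <- matrix(NA_real_, m, m)
  dimnames(rho) <- dimnames(p) <- list(vars, vars)
  diag(p) <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      st <- spearman_test(dataset[[vars[i]]], dataset[[vars[j]]],
                          method = method)
      rho[i, j] <- rho[j, i] <- st$rho
      p[i, j] <- p[j, i] <- st$p
    }
  }
  up <- upper.tri(p)
  flags <- if (correction == "bh") bh_correct(p[up], fdr = alpha) else
    p[up] <= alpha
  sig <- matrix(FALSE, m, m, dimnames = dimnames(p))
  sig[up] <- flags
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  blocks <- setNames(
    ifelse(vars %in% behavior_vars, "behavior", "fc"), vars
  )
  structure(
    list(rho = rho, p = p, significant = sig, blocks = blocks,
         dropped = dropped, alpha = alpha, method = method,
         correction = correction),
    class = "spearman_blocks"
  )
}

#' @export
print.spearman_blocks <- function(x, ...) {
  n_sig <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf(
    "<spearman_blocks> %d variables (%d fc, %d behavior) | %d significant pairs at alpha = %g (%s)\n",
    length(x$blocks), sum(x$blocks == "fc"), sum(x$blocks == "behavior"),
    n_sig, x$alpha, x$correction
  ))
  invisible(x)
}
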