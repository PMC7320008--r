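score_table <- function(scores, groups, ids = sprintf("r%02d", seq_along(scores)),
                        cohort = "test") {
  tibble::tibble(animal_id = ids, group = groups, cohort = cohort,
                 score = scores)
}

test_that("composite scores: sum mode adds pair correlations", {
  ds <- tibble::tibble(
    animal_id = sprintf("a%d", 1:6),
    group = rep(c("control", "arthritic"), each = 3),
    cohort = "test",
    p1 = c(0.9, 0.8, 0.85, 0.4, 0.35, 0.5),
    p2 = c(0.7, 0.75, 0.65, 0.2, 0.25, 0.3)
  )
  s1 <- composite_score(ds, "p1", mode = "sum")
  expect_equal(s1$score, ds$p1)
  s2 <- composite_score(ds, c("p1", "p2"), mode = "sum")
  expect_equal(s2$score, ds$p1 + ds$p2)
  expect_error(composite_score(ds, "nope", mode = "sum"), "nope")
})

test_that("logistic mode falls back to a ridge fit under separation", {
  set.seed(50)
  n <- 7
  ds <- tibble::tibble(
    animal_id = sprintf("a%d", 1:(2 * n)),
    group = rep(c("control", "arthritic"), each = n),
    cohort = "test",
    p1 = c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1)), # fully separated
    p2 = rnorm(2 * n)
  )
  expect_warning(
    sc <- composite_score(ds, c("p1", "p2"), mode = "logistic"),
    "separation"
  )
  expect_true(attr(sc, "ridged"))
  # ordering still separates the groups perfectly
  expect_equal(auc_bruteforce(sc$score, sc$group, "arthritic"), 1)

  # non-separated fit: plain MLE, no flag
  set.seed(51)
  ds2 <- ds
  ds2$p1 <- c(rnorm(n, 0.4, 1), rnorm(n, -0.4, 1))
  sc2 <- composite_score(ds2, c("p1", "p2"), mode = "logistic")
  expect_false(attr(sc2, "ridged"))
  expect_equal(length(attr(sc2, "coefficients")), 3)

  cst <- ds
  cst$p1 <- 1
  expect_error(composite_score(cst, "p1", mode = "logistic"),
               class = "fusfc_constant_predictor")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  r1 <- roc_curve(c(0.9, 0.8, 0.7, 0.4), c("a", "a", "c", "c"), positive = "a")
  expect_equal(r1$auc, auc_bruteforce(c(0.9, 0.8, 0.7, 0.4),
                                      c("a", "a", "c", "c"), "a"))
  # disjoint -> 1; identical values -> 0.5
  expect_equal(roc_curve(c(5, 6, 1, 2), c("a", "a", "c", "c"),
                         positive = "a")$auc, 1)
  expect_equal(roc_curve(c(3, 3, 3, 3), c("a", "a", "c", "c"),
                         positive = "a")$auc, 0.5)

  set.seed(52)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.1), 14, replace = TRUE) # forces ties
    g <- sample(rep(c("arthritic", "control"), c(9, 5)))
    rc <- roc_curve(s, g)
    # oracle on the oriented scores (auto-detected direction)
    oracle <- auc_bruteforce(s, g, "arthritic")
    if (rc$direction == "<=") oracle <- 1 - oracle
    expect_equal(rc$auc, oracle, tolerance = 1e-12)
    expect_true(all(diff(rc$points$fpr) >= 0))
    expect_true(all(diff(rc$points$tpr) >= 0))
    expect_true(rc$auc >= 0 && rc$auc <= 1)
    expect_true(rc$auc_ci[1] <= rc$auc && rc$auc <= rc$auc_ci[2])
  }
  expect_error(roc_curve(1:4, rep("a", 4)), class = "fusfc_one_class")
})

test_that("AUC confidence interval agrees with an independent DeLong oracle", {
  skip_if_not_installed("pROC")
  set.seed(53)
  s <- c(rnorm(9, 1), rnorm(9))
  g <- rep(c("arthritic", "control"), each = 9)
  rc <- roc_curve(s, g)
  pr <- pROC::roc(response = g, predictor = s, levels = c("control", "arthritic"),
                  direction = "<", quiet = TRUE)
  expect_equal(rc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(rc$auc_ci[1], max(0, ci[1]), tolerance = 1e-6)
  expect_equal(rc$auc_ci[2], min(1, ci[3]), tolerance = 1e-6)
})

test_that("nested logistic fits improve monotonically", {
  # the guaranteed nested-model property is non-increasing deviance;
  # in-sample AUC is additionally monotone once the groups separate
  deviance_of <- function(sc) {
    y <- as.integer(sc$group == "arthritic")
    p <- stats::plogis(sc$score)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }
  set.seed(54)
  n <- 12
  ds <- tibble::tibble(
    animal_id = sprintf("a%d", 1:(2 * n)),
    group = rep(c("control", "arthritic"), each = n),
    cohort = "test",
    p1 = c(rnorm(n, 0.5, 1), rnorm(n, -0.5, 1)),
    p2 = c(rnorm(n, 0.3, 1), rnorm(n, -0.3, 1)),
    p3 = rnorm(2 * n)
  )
  nested <- list("p1", c("p1", "p2"), c("p1", "p2", "p3"))
  devs <- purrr::map_dbl(nested, function(ps) {
    deviance_of(suppressWarnings(composite_score(ds, ps, mode = "logistic")))
  })
  expect_true(all(diff(devs) <= 1e-6))

  sep <- ds
  sep$p1 <- c(rnorm(n, 3, 0.3), rnorm(n, -3, 0.3)) # separating first pair
  aucs <- purrr::map_dbl(nested, function(ps) {
    roc_curve(suppressWarnings(composite_score(sep, ps, mode = "logistic")))$auc
  })
  expect_true(all(diff(aucs) >= -1e-6))
  expect_equal(aucs[1], 1)
})

test_that("Youden threshold reproduces the test-cohort operating shape", {
  # 9 arthritic vs 5 control, one control above every separating cut
  sc <- score_table(
    c(5, 6, 7, 8, 9, 10, 11, 12, 13, 1, 2, 3, 4, 6.5),
    rep(c("arthritic", "control"), c(9, 5))
  )
  rc <- select_threshold(roc_curve(sc))
  expect_equal(rc$direction, ">=")
  expect_equal(rc$operating$sensitivity, 1)
  expect_equal(rc$operating$specificity, 4 / 5)
  expect_equal(rc$operating$ppv, 9 / 10)
  expect_equal(rc$operating$npv, 1)
  # the cut sits at the midpoint of its empirical equivalence interval;
  # a score exactly at threshold counts as positive
  expect_equal(rc$chosen_threshold, 4.5)
  at_thr <- fusfc:::threshold_stats(c(4.5), "arthritic", 4.5, ">=", "arthritic")
  expect_equal(at_thr$sensitivity, 1)

  disj <- score_table(c(10, 11, 12, 1, 2, 3),
                      rep(c("arthritic", "control"), each = 3))
  rd <- select_threshold(roc_curve(disj))
  expect_equal(rd$operating$sensitivity, 1)
  expect_equal(rd$operating$specificity, 1)
})

test_that("external validation freezes the threshold and rejects overlap", {
  test_sc <- score_table(c(5, 6, 7, 8, 1, 2, 3),
                         rep(c("arthritic", "control"), c(4, 3)))
  rc <- select_threshold(roc_curve(test_sc))
  # validation: one of 8 arthritic below threshold -> sensitivity 7/8
  val <- score_table(
    c(4.5, 5.5, 6, 7, 8, 9, 10, 11, 1, 2, 3, 3.5),
    rep(c("arthritic", "control"), c(8, 4)),
    ids = sprintf("v%02d", 1:12), cohort = "validation"
  )
  val$score[1] <- 2.5 # the one miss
  st <- external_validate(rc, val)
  expect_equal(st$sensitivity, 7 / 8)
  expect_equal(st$specificity, 1)
  # invariant to row order
  st2 <- external_validate(rc, val[sample(nrow(val)), ])
  expect_equal(st, st2)

  overlap <- val
  overlap$animal_id[1] <- test_sc$animal_id[1]
  expect_error(external_validate(rc, overlap),
               class = "fusfc_cohort_overlap")
  expect_error(external_validate(roc_curve(test_sc), val), "select_threshold")
})
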