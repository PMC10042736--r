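test_that("AUC handles separation, symmetry and the pair-count example", {
  expect_equal(build_roc(rep(10, 5), rep(0, 5))$auc, 1.0)
  expect_equal(build_roc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(build_roc(c(3, 1), c(2, 0))$auc, 0.75)
  expect_error(build_roc(numeric(0), 1), "non-empty")
  expect_error(build_roc(c(1, NA), c(0, 1)), "non-finite")
})

test_that("trapezoid AUC equals the Mann-Whitney pair statistic with ties", {
  set.seed(303)
  for (rep in 1:50) {
    n_pos <- sample(2:40, 1); n_neg <- sample(2:40, 1)
    # coarse rounding forces plenty of ties, within and across classes
    pos <- round(rnorm(n_pos, 0.5, 1), sample(0:1, 1))
    neg <- round(rnorm(n_neg, 0, 1), sample(0:1, 1))
    roc <- build_roc(pos, neg)
    expect_lt(abs(roc$auc - pair_auc(pos, neg)), 1e-12)
  }
})

test_that("raising the threshold never increases TPR or FPR", {
  set.seed(304)
  for (rep in 1:20) {
    roc <- build_roc(rnorm(30, 1), round(rnorm(30), 1))
    expect_true(all(diff(roc$tpr) <= 0))
    expect_true(all(diff(roc$fpr) <= 0))
    expect_gte(roc$auc, 0); expect_lte(roc$auc, 1)
  }
})

test_that("Youden threshold of separated populations is the gap midpoint", {
  roc <- build_roc(c(10, 12, 14), c(0, 1, 2))
  thr <- select_threshold(roc, "youden")
  expect_equal(thr, (2 + 10) / 2)
  # applying it reproduces perfect separation
  expect_true(all(c(10, 12, 14) > thr) && all(c(0, 1, 2) < thr))
})

test_that("fixed_fpr respects the bound on a recount and fixed passes through", {
  set.seed(305)
  neg <- rnorm(100)
  pos <- rnorm(100, 2)
  roc <- build_roc(pos, neg)
  thr <- select_threshold(roc, "fixed_fpr", alpha = 0.05)
  expect_lte(mean(neg > thr), 0.05)
  expect_error(select_threshold(roc, "fixed_fpr", alpha = -0.1), "alpha")
  expect_equal(select_threshold(roc, "fixed", value = 1.23), 1.23)
})

test_that("AUC and curve agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(306)
  pos <- round(rnorm(60, 0.8), 1)
  neg <- round(rnorm(80), 1)
  roc <- build_roc(pos, neg)
  ref <- pROC::roc(response = c(rep(1, 60), rep(0, 80)),
                   predictor = c(pos, neg), quiet = TRUE,
                   direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("classification summarises percent expulsion with strict inequality", {
  s <- tibble::tibble(cell_id = 1:4, score = c(5, 5, 0, 0))
  res <- classify_and_summarize(s, threshold = 1)
  expect_equal(res$summary$percent_expulsion, 50)
  # ties at the threshold are negative calls
  tied <- classify_and_summarize(tibble::tibble(cell_id = 1, score = 1),
                                 threshold = 1)
  expect_false(tied$calls$call)
  # unscorable cells leave the denominator
  s2 <- tibble::tibble(cell_id = 1:3, score = c(5, NA, 0),
                       unscorable = c(FALSE, TRUE, FALSE))
  res2 <- classify_and_summarize(s2, threshold = 1)
  expect_equal(res2$summary$n_scored, 2)
  expect_equal(res2$summary$percent_expulsion, 50)
  expect_equal(res2$summary$n_unscorable, 1)
})

test_that("tidy and glance methods expose the curve and the summary", {
  roc <- build_roc(c(3, 1), c(2, 0))
  td <- tidy(roc)
  expect_named(td, c("threshold", "tpr", "fpr"))
  expect_equal(nrow(td), length(roc$thresholds))
  expect_equal(glance(roc)$auc, 0.75)
  res <- classify_and_summarize(tibble::tibble(cell_id = 1:2, score = c(2, 0)),
                                threshold = 1, condition = "WT")
  expect_equal(nrow(tidy(res)), 2)
  expect_equal(glance(res)$condition, "WT")
})

test_that("detection evaluation against ground truth recovers the confusion", {
  sim <- simulate_movie(small_config(fraction_expelling = 0.5, seed = 31))
  res <- analyze_movie(sim)
  # oracle calls copied from the truth via spatial matching
  first <- res$traces %>% dplyr::group_by(cell_id) %>%
    dplyr::slice_min(frame, n = 1) %>% dplyr::ungroup()
  truth0 <- dplyr::filter(sim$truth, frame == 0)
  nearest <- vapply(seq_len(nrow(first)), function(i) {
    d <- sqrt((truth0$row - first$row[i])^2 + (truth0$col - first$col[i])^2)
    truth0$cell_id[which.min(d)]
  }, numeric(1))
  truth_call <- sim$cells$expelled[match(nearest, sim$cells$cell_id)]
  perfect <- structure(list(
    calls = tibble::tibble(cell_id = first$cell_id, condition = "WT",
                           score = 1, call = truth_call),
    summary = tibble::tibble(), threshold = 0), class = "expulsion_result")
  ev <- evaluate_detection(perfect, sim, res$traces)
  expect_equal(ev$confusion$sensitivity, 1)
  expect_equal(ev$confusion$specificity, 1)

  none <- perfect
  none$calls$call <- FALSE
  ev0 <- evaluate_detection(none, sim, res$traces)
  expect_equal(ev0$confusion$sensitivity, 0)
  expect_equal(ev0$confusion$specificity, 1)
})

test_that("random calls produce false positives at the expected binomial rate", {
  sim <- simulate_movie(small_config(n_cells = 9, fraction_expelling = 0,
                                     seed = 33))
  res <- analyze_movie(sim)
  p <- 0.5
  fp <- 0; n_neg_total <- 0
  set.seed(34)
  for (rep in 1:40) {
    calls <- structure(list(
      calls = tibble::tibble(cell_id = unique(res$traces$cell_id),
                             condition = "KO", score = 1,
                             call = runif(length(unique(res$traces$cell_id))) < p),
      summary = tibble::tibble(), threshold = 0), class = "expulsion_result")
    ev <- evaluate_detection(calls, sim, res$traces)
    fp <- fp + ev$confusion$FP
    n_neg_total <- n_neg_total + ev$confusion$FP + ev$confusion$TN
  }
  expect_lt(abs(fp - p * n_neg_total),
            4 * sqrt(n_neg_total * p * (1 - p)))
})
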