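#' ROC curve from positive- and negative-population expulsion scores
#'
#' Builds a receiver operating characteristic curve for the expulsion score,
#' with a known-positive condition (e.g. Padi4 wild-type cells) against a
#' known-negative condition (Padi4 knockout). Whole conditions are used as
#' calibration classes exactly as in the imaging assay: every wild-type cell
#' counts as a positive even though not all of them expel, which is why
#' moderate false-positive rates are expected at the operating point.
#'
#' The curve is evaluated at every distinct score plus infinite endpoints; a
#' cell is called positive when its score is strictly greater than the
#' threshold, so TPR and FPR are nonincreasing in the threshold. The AUC is
#' the trapezoidal integral of TPR over FPR and equals the Mann-Whitney pair
#' statistic (ties counted 1/2).
#'
#' @param pos_scores,neg_scores Numeric vectors of finite per-cell scores.
#' @return An `expulsion_roc` object: `thresholds` (ascending, with -Inf and
#'   Inf), `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' build_roc(c(3, 1), c(2, 0))$auc  # 0.75
build_roc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    abort("build_roc: both score lists must be non-empty")
  for (nm in c("pos_scores", "neg_scores")) {
    v <- get(nm)
    if (any(!is.finite(v)))
      abort(sprintf("build_roc: non-finite score in %s (cell %d)",
                    nm, which(!is.finite(v))[1]))
  }
  thr <- c(-Inf, sort(unique(c(pos_scores, neg_scores))), Inf)
  tpr <- 1 - ecdf(pos_scores)(thr)     # P(score > thr)
  fpr <- 1 - ecdf(neg_scores)(thr)
  f <- rev(fpr); tp <- rev(tpr)        # fpr ascending 0 -> 1
  auc <- sum(diff(f) * (head(tp, -1) + tail(tp, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = length(pos_scores), n_neg = length(neg_scores),
                 chosen_threshold = NA_real_,
                 selection_method = NA_character_),
            class = "expulsion_roc")
}

#' @export
print.expulsion_roc <- function(x, ...) {
  cat(sprintf("<expulsion_roc> %d pos / %d neg cells, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  if (!is.na(x$chosen_threshold))
    cat(sprintf("  threshold %.6g (%s)\n", x$chosen_threshold,
                x$selection_method))
  invisible(x)
}

#' @describeIn build_roc Tidy the ROC curve into a tibble of
#'   (threshold, tpr, fpr).
#' @param x An `expulsion_roc`.
#' @param ... Unused.
#' @export
tidy.expulsion_roc <- function(x, ...) {
  tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' @describeIn build_roc One-row summary (auc, n_pos, n_neg, threshold).
#' @export
glance.expulsion_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
         chosen_threshold = x$chosen_threshold,
         selection_method = x$selection_method)
}

#' Select an operating threshold on an ROC curve
#'
#' `"youden"` (default) maximizes Youden's J = TPR - FPR over the score grid,
#' breaking ties towards the higher threshold, and returns the midpoint
#' between the optimal score and the next higher distinct score (so a
#' perfectly separating threshold sits mid-gap between the two populations).
#' `"fixed_fpr"` returns the smallest grid threshold whose FPR does not
#' exceed `alpha`. `"fixed"` passes `value` through unchanged.
#'
#' @param roc An `expulsion_roc` from [build_roc()].
#' @param method `"youden"`, `"fixed_fpr"`, or `"fixed"`.
#' @param alpha FPR bound for `"fixed_fpr"` (in `[0, 1]`).
#' @param value Threshold for `"fixed"`.
#' @return A single numeric score threshold.
#' @export
select_threshold <- function(roc, method = c("youden", "fixed_fpr", "fixed"),
                             alpha = NULL, value = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "expulsion_roc"))
  fin <- is.finite(roc$thresholds)
  thr <- roc$thresholds[fin]
  tpr <- roc$tpr[fin]
  fpr <- roc$fpr[fin]
  switch(method,
    youden = {
      j <- tpr - fpr
      best <- which(j >= max(j))
      i <- best[length(best)]                # ties -> higher threshold
      if (i < length(thr)) (thr[i] + thr[i + 1]) / 2 else thr[i]
    },
    fixed_fpr = {
      if (is.null(alpha) || alpha < 0 || alpha > 1)
        abort("fixed_fpr: alpha must be in [0, 1]")
      ok <- which(fpr <= alpha)
      if (!length(ok))
        abort("fixed_fpr: alpha below the achievable FPR floor")
      thr[min(ok)]
    },
    fixed = {
      if (is.null(value) || !is.finite(value))
        abort("fixed: a finite threshold value is required")
      value
    })
}

#' Classify cells and summarise percent expulsion per condition
#'
#' Calls a cell as undergoing nuclear expulsion when its score is strictly
#' greater than the threshold (ties are negative), then reports per-condition
#' counts and `percent_expulsion = 100 * n_positive_calls / n_scored`.
#' Unscorable cells are excluded from the denominator and reported.
#'
#' @param scores Score tibble (from [expulsion_scores()]) with columns
#'   `cell_id`, `score`, optionally `unscorable` and `condition`.
#' @param threshold Finite score threshold.
#' @param condition Optional single condition label applied to all cells when
#'   `scores` has no `condition` column.
#' @return An `expulsion_result`: list with `calls` (per-cell tibble:
#'   `cell_id`, `condition`, `score`, `call`), `summary` (per-condition
#'   tibble: `condition`, `n_cells`, `n_scored`, `n_unscorable`,
#'   `n_positive_calls`, `percent_expulsion`), and `threshold`.
#' @export
#' @examples
#' s <- tibble::tibble(cell_id = 1:4, score = c(5, 5, 0, 0))
#' classify_and_summarize(s, threshold = 1)$summary
classify_and_summarize <- function(scores, threshold, condition = NULL) {
  if (!is.finite(threshold)) abort("threshold must be finite")
  stopifnot(all(c("cell_id", "score") %in% names(scores)))
  dat <- as_tibble(scores)
  if (!"condition" %in% names(dat))
    dat$condition <- if (is.null(condition)) "all" else condition
  if (!"unscorable" %in% names(dat)) dat$unscorable <- is.na(dat$score)

  calls <- dat %>%
    mutate(call = !.data$unscorable & .data$score > threshold) %>%
    select("cell_id", "condition", "score", "call")
  summary <- dat %>%
    mutate(call = !.data$unscorable & .data$score > threshold) %>%
    group_by(.data$condition) %>%
    summarise(n_cells = dplyr::n(),
              n_scored = sum(!.data$unscorable),
              n_unscorable = sum(.data$unscorable),
              n_positive_calls = sum(.data$call),
              percent_expulsion = 100 * sum(.data$call) /
                pmax(1L, sum(!.data$unscorable)),
              .groups = "drop")
  structure(list(calls = calls, summary = summary, threshold = threshold),
            class = "expulsion_result")
}

#' @export
print.expulsion_result <- function(x, ...) {
  cat(sprintf("<expulsion_result> threshold %.6g\n", x$threshold))
  print(x$summary)
  invisible(x)
}

#' @describeIn classify_and_summarize Per-cell calls as a tibble.
#' @param x An `expulsion_result`.
#' @param ... Unused.
#' @export
tidy.expulsion_result <- function(x, ...) x$calls

#' @describeIn classify_and_summarize Per-condition summary as a tibble.
#' @export
glance.expulsion_result <- function(x, ...) x$summary

#' Confusion summary of expulsion calls against simulator ground truth
#'
#' Matches each trace to the ground-truth cell nearest to its first observed
#' position (greedy one-to-one, ascending distance, links farther than
#' `max_match_distance` forbidden) and tabulates calls against the true
#' `expelled` labels.
#'
#' @param result An `expulsion_result` from [classify_and_summarize()].
#' @param sim A `nucexpel_sim` from [simulate_movie()].
#' @param traces Trace tibble from [track_cells()] (positions used for
#'   matching).
#' @param max_match_distance Maximum trace-to-truth centroid distance
#'   (pixels).
#' @return List: `confusion` (tibble with TP, FP, FN, TN, sensitivity,
#'   specificity, balanced_accuracy), `matches` (trace cell_id to truth
#'   cell id), `n_unmatched_traces`, `n_unmatched_truth`.
#' @export
evaluate_detection <- function(result, sim, traces, max_match_distance = 10) {
  stopifnot(inherits(result, "expulsion_result"),
            inherits(sim, "nucexpel_sim"))
  first_pos <- traces %>%
    group_by(.data$cell_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup()
  # distances between each trace's first position and every truth cell at
  # that frame
  gt_frames <- split(sim$truth, sim$truth$frame)
  cand <- purrr::pmap(first_pos, function(cell_id, frame, row, col, ...) {
    gt <- gt_frames[[as.character(frame)]]
    if (is.null(gt)) return(NULL)
    d <- sqrt((gt$row - row)^2 + (gt$col - col)^2)
    tibble(trace_id = cell_id, truth_id = gt$cell_id, d = d)
  }) %>% bind_rows()
  cand <- filter(cand, .data$d <= max_match_distance)
  if (!nrow(cand))
    abort("evaluate_detection: no trace overlaps any ground-truth cell")
  cand <- arrange(cand, .data$d)
  matches <- list()
  used_tr <- used_gt <- integer()
  for (i in seq_len(nrow(cand))) {
    tr <- cand$trace_id[i]; gt <- cand$truth_id[i]
    if (tr %in% used_tr || gt %in% used_gt) next
    matches[[length(matches) + 1L]] <- tibble(trace_id = tr, truth_id = gt)
    used_tr <- c(used_tr, tr); used_gt <- c(used_gt, gt)
  }
  matches <- bind_rows(matches)

  dat <- result$calls %>%
    inner_join(matches, by = c(cell_id = "trace_id")) %>%
    inner_join(select(sim$cells, truth_id = "cell_id", "expelled"),
               by = "truth_id")
  tp <- sum(dat$call & dat$expelled)
  fp <- sum(dat$call & !dat$expelled)
  fn <- sum(!dat$call & dat$expelled)
  tn <- sum(!dat$call & !dat$expelled)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(confusion = tibble(TP = tp, FP = fp, FN = fn, TN = tn,
                          sensitivity = sens, specificity = spec,
                          balanced_accuracy = mean(c(sens, spec))),
       matches = matches,
       n_unmatched_traces = dplyr::n_distinct(result$calls$cell_id) -
         nrow(matches),
       n_unmatched_truth = nrow(sim$cells) - nrow(matches))
}
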