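#' Baseline-normalize chromatin area traces
#'
#' Converts raw per-cell area traces into chromatin-expansion traces
#' `e(t) = area(t) / baseline_area`, where the baseline is the median area
#' over the frames of `baseline_window` that the cell was observed in
#' (typically the frames before drug addition). Cells with no observed
#' baseline frame, or a non-positive baseline, are excluded (not an error)
#' and tallied in the `"excluded"` attribute of the result.
#'
#' @param traces Trace tibble from [track_cells()] (columns `cell_id`,
#'   `frame`, `area`, ...).
#' @param baseline_window Inclusive 0-based frame range `c(first, last)`.
#' @return Tibble with `cell_id`, `frame`, `area`, `e`, `baseline_area`.
#'   Attribute `excluded`: tibble of `cell_id`, `reason` (`"no_baseline"` or
#'   `"nonpositive_baseline"`).
#' @export
#' @examples
#' tr <- tibble::tibble(cell_id = 1, frame = 0:3, area = c(100, 100, 100, 300))
#' normalize_traces(tr, baseline_window = c(0, 2))
normalize_traces <- function(traces, baseline_window = c(0, 4)) {
  stopifnot(all(c("cell_id", "frame", "area") %in% names(traces)))
  base <- traces %>%
    filter(.data$frame >= baseline_window[1],
           .data$frame <= baseline_window[2]) %>%
    group_by(.data$cell_id) %>%
    summarise(baseline_area = median(.data$area), .groups = "drop")

  all_cells <- distinct(traces, .data$cell_id)
  excluded <- all_cells %>%
    left_join(base, by = "cell_id") %>%
    mutate(reason = dplyr::case_when(
      is.na(.data$baseline_area) ~ "no_baseline",
      .data$baseline_area <= 0 ~ "nonpositive_baseline",
      TRUE ~ NA_character_)) %>%
    filter(!is.na(.data$reason)) %>%
    select("cell_id", "reason")

  out <- traces %>%
    inner_join(filter(base, .data$baseline_area > 0), by = "cell_id") %>%
    mutate(e = .data$area / .data$baseline_area) %>%
    select("cell_id", "frame", "area", "e", "baseline_area")
  attr(out, "excluded") <- excluded
  out
}

#' Per-cell expulsion score: maximum gradient of chromatin expansion
#'
#' The expulsion score of a cell is the maximum numerical gradient of its
#' chromatin-expansion trace over a grid of time intervals:
#' `score = max over (t, w) of (e(t + w) - e(t)) / w`, with `w` ranging over
#' `intervals` (frames) and `t` over all frames where both endpoints were
#' observed. The forward difference is used deliberately -- the score is the
#' maximum increase in size per frame, not a smoothed derivative. Exact ties
#' are broken by earliest `t`, then smallest `w`. A cell whose trace has no
#' valid `(t, w)` pair for any interval is flagged unscorable.
#'
#' @param expansion Expansion tibble from [normalize_traces()] (columns
#'   `cell_id`, `frame`, `e`).
#' @param intervals Integer vector of interval widths in frames (>= 1). The
#'   dyadic default spans both fast (ionophore-like) and slow
#'   (Raptinal-like) expansion kinetics.
#' @return Tibble: `cell_id`, `score`, `argmax_time` (the `t` attaining the
#'   maximum, 0-based), `argmax_interval`, `onset_time` (earliest window
#'   start with gradient within 10% of the maximum; a noise-robust expulsion
#'   onset), `n_frames` (observed frames), `unscorable`.
#' @export
#' @examples
#' e <- tibble::tibble(cell_id = 1, frame = 0:4, e = c(1, 1, 1, 4, 4))
#' expulsion_scores(e, intervals = c(1, 2))  # score 3 at t = 2, w = 1
expulsion_scores <- function(expansion, intervals = c(1, 2, 4, 8)) {
  stopifnot(all(c("cell_id", "frame", "e") %in% names(expansion)),
            all(intervals >= 1))
  intervals <- sort(unique(as.integer(intervals)))
  lhs <- expansion %>% select("cell_id", "frame", "e")
  rhs <- lhs %>% dplyr::rename(frame2 = "frame", e2 = "e")

  grads <- purrr::map(intervals, function(w) {
    lhs %>%
      mutate(frame2 = .data$frame + w) %>%
      inner_join(rhs, by = c("cell_id", "frame2")) %>%
      transmute(.data$cell_id, t = .data$frame, w = w,
                grad = (.data$e2 - .data$e) / w)
  }) %>% bind_rows()

  best <- grads %>%
    arrange(.data$cell_id, dplyr::desc(.data$grad), .data$t, .data$w) %>%
    group_by(.data$cell_id) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select("cell_id", score = "grad", argmax_time = "t", argmax_interval = "w")

  # Robust onset: earliest window start whose gradient is within 10% of the
  # maximum. On a noisy linear ramp every full-ramp window has near-equal
  # slope, so the strict argmax lands anywhere on the ramp; the earliest
  # near-maximal start pins the onset to the foot of the rise.
  onset <- if (nrow(grads)) {
    grads %>%
      inner_join(select(best, "cell_id", "score"), by = "cell_id") %>%
      filter(.data$grad >= .data$score - 0.1 * abs(.data$score)) %>%
      group_by(.data$cell_id) %>%
      summarise(onset_time = min(.data$t), .groups = "drop")
  } else {
    tibble(cell_id = grads$cell_id, onset_time = integer())
  }

  counts <- expansion %>% count(.data$cell_id, name = "n_frames")
  counts %>%
    left_join(best, by = "cell_id") %>%
    left_join(onset, by = "cell_id") %>%
    mutate(unscorable = is.na(.data$score)) %>%
    select("cell_id", "score", "argmax_time", "argmax_interval",
           "onset_time", "n_frames", "unscorable")
}

#' Per-frame median chromatin expansion across cells
#'
#' Element-wise median of the expansion traces over all cells observed at
#' each frame; frames with no observations are omitted. With
#' `align = "onset"` each cell's frames are first shifted by its expulsion
#' onset (`argmax_time` from [expulsion_scores()]) so that time 0 is the
#' onset.
#'
#' @param expansion Expansion tibble from [normalize_traces()].
#' @param align `"absolute"` (movie frame) or `"onset"` (onset-aligned).
#' @param onsets Tibble with `cell_id`, `argmax_time` (required for
#'   `align = "onset"`); cells without an onset are dropped.
#' @return Tibble: `frame` (or onset-relative frame), `median_e`, `n`.
#' @export
median_expansion <- function(expansion, align = c("absolute", "onset"),
                             onsets = NULL) {
  align <- match.arg(align)
  if (!nrow(expansion)) abort("median_expansion: empty input")
  dat <- expansion
  if (align == "onset") {
    if (is.null(onsets)) abort("onsets required for align = 'onset'")
    dat <- dat %>%
      inner_join(select(onsets, "cell_id", "argmax_time"), by = "cell_id") %>%
      filter(!is.na(.data$argmax_time)) %>%
      mutate(frame = .data$frame - .data$argmax_time)
    if (!nrow(dat)) abort("median_expansion: no cells with onset")
  }
  dat %>%
    group_by(.data$frame) %>%
    summarise(median_e = median(.data$e), n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$frame)
}
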