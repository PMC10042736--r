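#' Measure per-cell calcium inside the nuclear mask
#'
#' For every tracked cell and frame, computes the mean calcium-channel
#' intensity over that cell's segmented nuclear mask (the chromatin-reporter
#' mask defines the measurement region, as in the imaging assay), then
#' normalizes by the per-cell baseline: `c(t) = intensity(t) / baseline`,
#' baseline being the median raw intensity over the baseline window. Frames
#' where a cell has no mask are absent from its trace (missing, not zero).
#' Cells with no baseline frames are excluded and tallied in the `excluded`
#' attribute.
#'
#' @param movie A [movie_stack()] containing a calcium channel.
#' @param frames List of `labeled_frame` objects (see [segment_movie()]).
#' @param traces Trace tibble from [track_cells()]; its `label` column maps
#'   cells to mask labels per frame.
#' @param baseline_window Inclusive 0-based frame range for the baseline.
#' @param channel Calcium channel index (1-based within the movie array).
#' @return Tibble: `cell_id`, `frame`, `raw`, `c` (normalized), `baseline`.
#' @export
measure_calcium <- function(movie, frames, traces, baseline_window = c(0, 4),
                            channel = 2L) {
  stopifnot(inherits(movie, "movie_stack"))
  if (n_channels(movie) < channel)
    abort("measure_calcium: movie has no calcium channel")

  per_frame <- purrr::map(frames, function(lf) {
    lab <- lf$labels
    nz <- which(lab > 0L)
    if (!length(nz)) return(NULL)
    ca <- movie[, , lf$frame + 1L, channel]
    sums <- rowsum(ca[nz], lab[nz])
    cnts <- rowsum(rep(1, length(nz)), lab[nz])
    tibble(frame = lf$frame,
           label = as.integer(rownames(sums)),
           raw = as.vector(sums) / as.vector(cnts))
  }) %>% bind_rows()

  out <- traces %>%
    select("cell_id", "frame", "label") %>%
    inner_join(per_frame, by = c("frame", "label"))

  base <- out %>%
    filter(.data$frame >= baseline_window[1],
           .data$frame <= baseline_window[2]) %>%
    group_by(.data$cell_id) %>%
    summarise(baseline = median(.data$raw), .groups = "drop") %>%
    filter(.data$baseline > 0)

  excluded <- tibble(
    cell_id = setdiff(unique(out$cell_id), base$cell_id),
    reason = "no_baseline")
  res <- out %>%
    inner_join(base, by = "cell_id") %>%
    mutate(c = .data$raw / .data$baseline) %>%
    select("cell_id", "frame", "raw", "c", "baseline")
  attr(res, "excluded") <- excluded
  res
}

#' Detect calcium spikes in normalized calcium traces
#'
#' A spike is the first frame at which the normalized calcium `c(t)` stays at
#' or above `spike_fold` for at least `min_run` consecutive observed frames
#' (consecutive in frame index, so gaps break a run). Returns one row per
#' cell; `spike_frame` is `NA` when no spike qualifies.
#'
#' @param calcium Calcium tibble from [measure_calcium()].
#' @param spike_fold Fold-over-baseline threshold.
#' @param min_run Minimum consecutive frames at or above threshold.
#' @return Tibble: `cell_id`, `spike_frame` (0-based or NA), `peak_fold`.
#' @export
#' @examples
#' ca <- tibble::tibble(cell_id = 1, frame = 0:5,
#'                      c = c(1, 1, 2, 2, 1, 1), raw = 0, baseline = 1)
#' detect_spikes(ca)  # spike at frame 2
detect_spikes <- function(calcium, spike_fold = 1.5, min_run = 2) {
  stopifnot(all(c("cell_id", "frame", "c") %in% names(calcium)))
  calcium %>%
    arrange(.data$cell_id, .data$frame) %>%
    group_by(.data$cell_id) %>%
    summarise(spike_frame = {
      ok <- .data$c >= spike_fold
      fr <- .data$frame
      run_first <- NA_integer_
      # split at unobserved frames so gaps break runs
      for (g in split(seq_along(fr), cumsum(c(1, diff(fr) != 1)))) {
        r <- rle(ok[g])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        hit <- which(r$values & r$lengths >= min_run)
        if (length(hit)) { run_first <- fr[g[starts[hit[1]]]]; break }
      }
      run_first
    },
    peak_fold = max(.data$c), .groups = "drop")
}

#' Timing of calcium spikes relative to expulsion onset
#'
#' For each cell with both a detected calcium spike and an expulsion onset
#' (the score's `onset_time`, falling back to `argmax_time` when absent),
#' computes `lag = spike_frame - expulsion_onset` (negative means the spike
#' precedes expulsion) and summarises the population: median lag and the
#' fraction of cells whose spike precedes onset. When `calls` is supplied,
#' only cells called as expelling are included; with zero such cells the
#' summary is empty (`n = 0`).
#'
#' @param spikes Spike tibble from [detect_spikes()].
#' @param scores Score tibble from [expulsion_scores()].
#' @param calls Optional per-cell calls tibble (`cell_id`, `call`) from an
#'   `expulsion_result`; restricts the summary to expelling cells.
#' @return List: `per_cell` (tibble `cell_id`, `spike_frame`, `onset`,
#'   `lag`), `summary` (tibble `n`, `median_lag`, `frac_spike_first`).
#' @export
spike_expulsion_lag <- function(spikes, scores, calls = NULL) {
  onset_col <- if ("onset_time" %in% names(scores)) "onset_time"
               else "argmax_time"
  dat <- spikes %>%
    inner_join(select(scores, "cell_id", onset = dplyr::all_of(onset_col)),
               by = "cell_id") %>%
    filter(!is.na(.data$spike_frame), !is.na(.data$onset))
  if (!is.null(calls)) {
    dat <- dat %>%
      inner_join(select(calls, "cell_id", "call"), by = "cell_id") %>%
      filter(.data$call) %>%
      select(-"call")
  }
  per_cell <- dat %>%
    mutate(lag = .data$spike_frame - .data$onset) %>%
    select("cell_id", "spike_frame", "onset", "lag")
  summary <- if (nrow(per_cell)) {
    tibble(n = nrow(per_cell), median_lag = median(per_cell$lag),
           frac_spike_first = mean(per_cell$lag < 0))
  } else {
    tibble(n = 0L, median_lag = NA_real_, frac_spike_first = NA_real_)
  }
  list(per_cell = per_cell, summary = summary)
}
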