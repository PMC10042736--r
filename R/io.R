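#' Read and write movie stacks as multi-page TIFF
#'
#' Movies are written channel-major (all frames of channel 1, then channel 2,
#' ...) as 16-bit pages; intensities are rounded to integer counts and must
#' be below 65535. A sidecar is not written here -- [run_pipeline()] stores
#' the resolved configuration as JSON alongside.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [movie_stack()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  if (max(movie) >= 65535) abort("intensities exceed 16-bit range")
  pages <- list()
  for (ch in seq_len(n_channels(movie)))
    for (f in seq_len(n_frames(movie)))
      pages[[length(pages) + 1L]] <- round(movie[, , f, ch]) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write per-frame label images as a 16-bit multi-page TIFF
#'
#' @param frames List of `labeled_frame` objects (see [segment_movie()]).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(frames, path) {
  pages <- lapply(frames, function(lf) lf$labels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a simulated movie bundle to a directory
#'
#' Writes the movie as a channel-major multi-page TIFF (`movie.tif`), the
#' per-cell ground-truth table (`ground_truth.csv`: `cell_id`, `expelled`,
#' `apoptotic`, `condensation_onset`, `expulsion_onset`,
#' `calcium_spike_frame`), the per-frame true centroids and areas
#' (`truth_frames.csv`) and the resolved configuration (`config.json`).
#'
#' @param sim A `nucexpel_sim` from [simulate_movie()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "nucexpel_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_movie_tiff(sim$movie, file.path(dir, "movie.tif"))
  readr::write_csv(
    sim$cells[, c("cell_id", "expelled", "apoptotic", "condensation_onset",
                  "expulsion_onset", "calcium_spike_frame")],
    file.path(dir, "ground_truth.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth_frames.csv"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @rdname write_movie_tiff
#' @param n_channels Number of channels the pages are divided into.
#' @param channel_names,frame_interval,pixel_size Metadata for the
#'   reconstructed [movie_stack()].
#' @export
read_movie_tiff <- function(path, n_channels = 1L,
                            channel_names = paste0("ch",
                                                   seq_len(n_channels) - 1),
                            frame_interval = 1, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% n_channels != 0)
    abort("page count is not a multiple of n_channels")
  nf <- length(pages) %/% n_channels
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(h, w, nf, n_channels))
  k <- 1L
  for (ch in seq_len(n_channels))
    for (f in seq_len(nf)) {
      arr[, , f, ch] <- round(pages[[k]] * 65535)
      k <- k + 1L
    }
  movie_stack(arr, channel_names = channel_names,
              frame_interval = frame_interval, pixel_size = pixel_size)
}
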