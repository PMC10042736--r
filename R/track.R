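#' Link segmented nuclei across frames into per-cell traces
#'
#' Greedy nearest-neighbour linking by centroid distance. At each frame the
#' globally closest (track, detection) pair within `max_link_distance` is
#' linked first and removed, then the next closest, and so on; exact distance
#' ties are broken by smaller area difference, then lower detection label,
#' then lower track id. A detection is assigned to at most one track.
#' Unmatched detections open new tracks. A track unmatched for `max_gap`
#' consecutive frames is closed with `end_reason = "lost"`; tracks alive at
#' the last frame end with `end_reason = "movie_end"`.
#'
#' @param frames List of `labeled_frame` objects in frame order (see
#'   [segment_movie()]).
#' @param max_link_distance Maximum centroid displacement (pixels) allowed for
#'   a frame-to-frame link.
#' @param max_gap Number of consecutive missed frames after which a track is
#'   closed.
#' @return A tibble with one row per (cell, frame): `cell_id`, `frame`
#'   (0-based), `row`, `col`, `area`, `label`, any `mean_*` channel columns,
#'   and `end_reason` (constant within a cell, one of `"movie_end"`,
#'   `"lost"`).
#' @export
track_cells <- function(frames, max_link_distance = 15, max_gap = 2) {
  if (!length(frames)) abort("empty frame sequence")
  stopifnot(all(vapply(frames, inherits, logical(1), "labeled_frame")))

  mean_cols <- grep("^mean_", names(frames[[1]]$regions), value = TRUE)
  keep_cols <- c("row", "col", "area", "label", mean_cols)
  active <- list()     # each: id, row, col, area, last_frame, missed
  next_id <- 1L
  rows <- vector("list", length(frames))
  end_reason <- list()

  for (f in seq_along(frames)) {
    lf <- frames[[f]]
    det <- lf$regions
    n_act <- length(active)
    n_det <- nrow(det)
    assign_id <- rep(NA_integer_, n_det)
    matched_act <- rep(FALSE, n_act)

    if (n_act > 0 && n_det > 0) {
      arow <- vapply(active, `[[`, numeric(1), "row")
      acol <- vapply(active, `[[`, numeric(1), "col")
      aarea <- vapply(active, `[[`, numeric(1), "area")
      D <- sqrt(outer(arow, det$row, "-")^2 + outer(acol, det$col, "-")^2)
      D[D > max_link_distance] <- Inf
      repeat {
        dmin <- min(D)
        if (!is.finite(dmin)) break
        cand <- which(D <= dmin, arr.ind = TRUE)
        if (nrow(cand) > 1) {
          adiff <- abs(aarea[cand[, 1]] - det$area[cand[, 2]])
          cand <- cand[order(adiff, det$label[cand[, 2]], cand[, 1]), ,
                       drop = FALSE]
        }
        ai <- cand[1, 1]; di <- cand[1, 2]
        matched_act[ai] <- TRUE
        assign_id[di] <- active[[ai]]$id
        active[[ai]][c("row", "col", "area")] <-
          list(det$row[di], det$col[di], det$area[di])
        active[[ai]]$last_frame <- lf$frame
        active[[ai]]$missed <- 0L
        D[ai, ] <- Inf; D[, di] <- Inf
      }
    }

    if (n_det > 0) {
      for (di in which(is.na(assign_id))) {
        assign_id[di] <- next_id
        active[[length(active) + 1L]] <- list(
          id = next_id, row = det$row[di], col = det$col[di],
          area = det$area[di], last_frame = lf$frame, missed = 0L)
        next_id <- next_id + 1L
      }
      rows[[f]] <- cbind(tibble(cell_id = assign_id, frame = lf$frame),
                         det[, keep_cols])
    }

    if (n_act > 0) {
      closed <- integer()
      for (ai in which(!matched_act)) {
        active[[ai]]$missed <- active[[ai]]$missed + 1L
        if (active[[ai]]$missed >= max_gap) closed <- c(closed, ai)
      }
      for (ai in closed) end_reason[[as.character(active[[ai]]$id)]] <- "lost"
      if (length(closed)) active <- active[-closed]
    }
  }

  last_frame <- frames[[length(frames)]]$frame
  for (tr in active) {
    end_reason[[as.character(tr$id)]] <-
      if (tr$last_frame == last_frame) "movie_end" else "lost"
  }

  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- tibble(cell_id = integer(), frame = integer(), row = double(),
                  col = double(), area = double(), label = integer())
    for (nm in mean_cols) out[[nm]] <- double()
    out$end_reason <- character()
    return(out)
  }
  traces <- as_tibble(bind_rows(rows))
  er <- tibble(cell_id = as.integer(names(end_reason)),
               end_reason = unlist(end_reason, use.names = FALSE))
  traces %>%
    left_join(er, by = "cell_id") %>%
    arrange(.data$cell_id, .data$frame)
}
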