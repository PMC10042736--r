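#' Multi-channel movie container
#'
#' A light wrapper around a 4-D numeric array indexed
#' `[row, col, frame, channel]` with acquisition metadata. All intensities are
#' non-negative counts. Frames are indexed 0-based in every exported table;
#' the array itself uses R's native 1-based indexing.
#'
#' @param x Numeric 4-D array `[row, col, frame, channel]`.
#' @param channel_names Character vector, one name per channel.
#' @param frame_interval Minutes between frames.
#' @param pixel_size Optional pixel size in micrometres.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(x, channel_names = paste0("ch", seq_len(dim(x)[4]) - 1),
                        frame_interval = 1, pixel_size = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 4)
  if (any(x < 0)) abort("movie intensities must be >= 0")
  if (length(channel_names) != dim(x)[4])
    abort("one channel name per channel required")
  structure(x, channel_names = channel_names, frame_interval = frame_interval,
            pixel_size = pixel_size, class = c("movie_stack", "array"))
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<movie_stack> %d x %d px, %d frames, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4],
              paste(attr(x, "channel_names"), collapse = ", ")))
  invisible(x)
}

#' Number of frames / channels in a movie stack
#' @param movie A [movie_stack()].
#' @return Integer count.
#' @export
n_frames <- function(movie) dim(movie)[3]

#' @rdname n_frames
#' @export
n_channels <- function(movie) dim(movie)[4]

# Intensity patch of one smooth-edged elliptical blob, clipped to the frame.
# rho = 1 is the ground-truth contour; the profile is amp / (1 + exp((rho-1)/s))
# so the half-maximum contour encloses exactly pi * rx * ry pixels. Returns
# NULL when the blob falls outside the frame; the caller adds the patch in
# place to avoid copying the full frame per blob.
blob_patch <- function(h, w, cy, cx, ry, rx, theta, amp, s) {
  pad <- ceiling(max(ry, rx) * (1 + 8 * s)) + 1L
  r0 <- max(1L, floor(cy - pad)); r1 <- min(h, ceiling(cy + pad))
  c0 <- max(1L, floor(cx - pad)); c1 <- min(w, ceiling(cx + pad))
  if (r0 > r1 || c0 > c1) return(NULL)
  yy <- (r0:r1) - cy
  xx <- (c0:c1) - cx
  ct <- cos(theta); st <- sin(theta)
  ny <- length(yy); nx <- length(xx)
  X <- matrix(xx, ny, nx, byrow = TRUE)
  Y <- matrix(yy, ny, nx)
  U <- (ct * X + st * Y) / rx
  V <- (-st * X + ct * Y) / ry
  rho <- sqrt(U * U + V * V)
  list(r0 = r0, r1 = r1, c0 = c0, c1 = c1,
       patch = amp / (1 + exp((rho - 1) / s)))
}

# Add one blob to an intensity matrix (used for small test images).
render_blob <- function(img, cy, cx, ry, rx, theta, amp, s) {
  p <- blob_patch(nrow(img), ncol(img), cy, cx, ry, rx, theta, amp, s)
  if (is.null(p)) return(img)
  img[p$r0:p$r1, p$c0:p$c1] <- img[p$r0:p$r1, p$c0:p$c1] + p$patch
  img
}

# Per-cell state timeline: draws all stochastic per-cell parameters from the
# cell's own substream and returns body geometry per frame plus ground truth.
cell_timeline <- function(cfg, i) {
  set.seed(derive_seed(cfg$seed, i))
  u_fate <- runif(1)
  r <- max(3, rnorm(1, cfg$baseline_radius_mean, cfg$baseline_radius_sd))
  aspect <- exp(rnorm(1, 0, cfg$aspect_sd))
  rx <- r * sqrt(aspect); ry <- r / sqrt(aspect)
  theta <- runif(1, 0, pi)
  amp <- max(300, rnorm(1, cfg$nuclear_amp_mean, cfg$nuclear_amp_sd))
  pos_jitter <- runif(2, -0.15, 0.15)
  c_onset <- sample(seq(cfg$condensation_onset_range[1],
                        cfg$condensation_onset_range[2]), 1)
  e_delay <- sample(seq(cfg$expulsion_delay_range[1],
                        cfg$expulsion_delay_range[2]), 1)
  frag_u <- runif(1)
  k_bodies <- sample(2:4, 1)
  share <- runif(k_bodies); share <- share / sum(share)
  body_dist <- runif(k_bodies, 0.3, 0.75) * 2 * r
  body_ang <- runif(k_bodies, 0, 2 * pi)
  jitter <- exp(rnorm(cfg$n_frames, 0, cfg$area_jitter_sd))
  drift_y <- c(0, cumsum(rnorm(cfg$n_frames - 1, 0, cfg$drift_sd)))
  drift_x <- c(0, cumsum(rnorm(cfg$n_frames - 1, 0, cfg$drift_sd)))

  expelled <- u_fate < cfg$fraction_expelling
  apoptotic <- u_fate < cfg$fraction_apoptotic
  fragments <- apoptotic && frag_u < cfg$fragmentation_prob
  e_onset <- c_onset + e_delay
  A0 <- pi * rx * ry
  cf <- cfg$condensation_fold
  cd <- max(1L, cfg$condensation_duration)

  t <- seq_len(cfg$n_frames) - 1L    # 0-based frames
  area <- rep(A0, cfg$n_frames)
  if (apoptotic) {
    j <- t - c_onset
    sel <- j >= 0
    prog <- pmin(1, (j[sel] + 1) / cd)
    area[sel] <- A0 * (1 - prog * (1 - cf))
  }
  frag_on <- rep(FALSE, cfg$n_frames)
  if (fragments) frag_on <- apoptotic & (t >= c_onset + cd)
  if (expelled) {
    j <- t - e_onset
    sel <- j >= 0
    if (any(sel)) {
      a_start <- area[which(sel)[1]]
      prog <- pmin(1, (j[sel] + 1) / max(1L, cfg$expansion_duration))
      area[sel] <- a_start + prog * (cfg$expansion_fold * A0 - a_start)
      frag_on[sel] <- FALSE           # bodies coalesce at expulsion
    }
  }
  area <- area * jitter

  list(
    expelled = expelled, apoptotic = apoptotic, fragments = fragments,
    condensation_onset = if (apoptotic) c_onset else NA_integer_,
    expulsion_onset = if (expelled) e_onset else NA_integer_,
    calcium_spike_frame = if (apoptotic) e_onset - cfg$calcium_spike_lead
                          else NA_integer_,
    rx = rx, ry = ry, theta = theta, amp = amp, A0 = A0,
    pos_jitter = pos_jitter, area = area, frag_on = frag_on,
    k_bodies = k_bodies, share = share,
    body_dy = body_dist * sin(body_ang), body_dx = body_dist * cos(body_ang),
    drift_y = drift_y, drift_x = drift_x
  )
}

#' Simulate a nuclear-expulsion time-lapse movie with ground truth
#'
#' Renders a seeded, fully deterministic movie of nuclei following the
#' phenotype sequence baseline -> apoptotic condensation (optional
#' fragmentation into apoptotic bodies) -> for expelling cells, monotone
#' chromatin-area growth to `expansion_fold` times baseline with conserved
#' integrated intensity. If `config$calcium_enabled`, a second channel renders
#' per-cell calcium with a sustained fold-increase starting
#' `calcium_spike_lead` frames before expulsion onset. Poisson photon noise
#' and Gaussian read noise are added unless `noise = FALSE`.
#'
#' @param config A [simulation_config()].
#' @param noise Add photon and read noise? Disable for noiseless ground-truth
#'   validation images.
#' @return A `nucexpel_sim` list: `movie` ([movie_stack()]), `cells` (tibble of
#'   per-cell ground truth: `cell_id`, `expelled`, `apoptotic`,
#'   `condensation_onset`, `expulsion_onset`, `calcium_spike_frame`,
#'   `baseline_area`, `row0`, `col0`), `truth` (tibble of per-frame true
#'   centroid and area: `cell_id`, `frame`, `row`, `col`, `area`), and
#'   `config`. Frames and coordinates are 0-based.
#' @export
#' @examples
#' sim <- simulate_movie(simulation_config(
#'   n_cells = 4, frame_height = 160, frame_width = 160, n_frames = 24,
#'   condensation_onset_range = c(8, 10), fraction_apoptotic = 1,
#'   fraction_expelling = 1, seed = 1))
#' sim$cells
simulate_movie <- function(config, noise = TRUE) {
  cfg <- validate_simulation_config(config)
  h <- cfg$frame_height; w <- cfg$frame_width; nf <- cfg$n_frames
  spacing <- cfg$cell_spacing * cfg$baseline_radius_mean
  ncol_grid <- max(1L, floor(w / spacing))
  nrow_grid <- max(1L, floor(h / spacing))
  if (cfg$n_cells > ncol_grid * nrow_grid)
    abort(sprintf(
      "frame too small: %d grid positions at spacing %.1f px for %d cells",
      ncol_grid * nrow_grid, spacing, cfg$n_cells),
      class = "nucexpel_config_error")

  cells <- vector("list", cfg$n_cells)
  truth_rows <- vector("list", cfg$n_cells)
  bodies_by_frame <- vector("list", nf)   # nuclear-channel render list
  for (f in seq_len(nf)) bodies_by_frame[[f]] <- list()
  ca_by_frame <- if (cfg$calcium_enabled) bodies_by_frame else NULL

  for (i in seq_len(cfg$n_cells)) {
    tl <- cell_timeline(cfg, i)
    gy <- ((i - 1) %/% ncol_grid)
    gx <- ((i - 1) %% ncol_grid)
    base_y <- (gy + 0.5 + tl$pos_jitter[1]) * spacing
    base_x <- (gx + 0.5 + tl$pos_jitter[2]) * spacing

    t <- seq_len(nf) - 1L
    cy <- base_y + tl$drift_y
    cx <- base_x + tl$drift_x
    amp_t <- tl$amp * tl$A0 / tl$area           # intensity conservation
    scale1 <- sqrt(tl$area / tl$A0)

    spike_on <- if (cfg$calcium_enabled && !is.na(tl$calcium_spike_frame))
      t >= tl$calcium_spike_frame else rep(FALSE, nf)
    ca_amp_t <- cfg$calcium_amp * ifelse(spike_on, cfg$calcium_spike_fold, 1)

    true_row <- cy; true_col <- cx
    for (f in seq_len(nf)) {
      if (tl$frag_on[f]) {
        areas <- tl$share * tl$area[f]
        sc <- sqrt(areas / tl$A0)
        by <- cy[f] + tl$body_dy; bx <- cx[f] + tl$body_dx
        bod <- cbind(cy = by, cx = bx, ry = tl$ry * sc, rx = tl$rx * sc,
                     theta = tl$theta, amp = amp_t[f])
        true_row[f] <- sum(areas * by) / sum(areas)
        true_col[f] <- sum(areas * bx) / sum(areas)
      } else {
        bod <- cbind(cy = cy[f], cx = cx[f], ry = tl$ry * scale1[f],
                     rx = tl$rx * scale1[f], theta = tl$theta, amp = amp_t[f])
      }
      bodies_by_frame[[f]][[length(bodies_by_frame[[f]]) + 1L]] <- bod
      if (cfg$calcium_enabled) {
        cab <- bod
        cab[, "ry"] <- cab[, "ry"] * 1.3
        cab[, "rx"] <- cab[, "rx"] * 1.3
        cab[, "amp"] <- ca_amp_t[f]
        ca_by_frame[[f]][[length(ca_by_frame[[f]]) + 1L]] <- cab
      }
    }

    cells[[i]] <- tibble(
      cell_id = i, expelled = tl$expelled, apoptotic = tl$apoptotic,
      condensation_onset = tl$condensation_onset,
      expulsion_onset = tl$expulsion_onset,
      calcium_spike_frame = tl$calcium_spike_frame,
      baseline_area = tl$A0, row0 = base_y - 1, col0 = base_x - 1)
    truth_rows[[i]] <- tibble(
      cell_id = i, frame = t, row = true_row - 1, col = true_col - 1,
      area = tl$area)
  }

  nch <- if (cfg$calcium_enabled) 2L else 1L
  arr <- array(0, dim = c(h, w, nf, nch))
  render_channel <- function(frames_list) {
    out <- array(0, dim = c(h, w, nf))
    for (f in seq_len(nf)) {
      img <- matrix(cfg$background_level, h, w)
      for (bod in frames_list[[f]])
        for (b in seq_len(nrow(bod))) {
          p <- blob_patch(h, w, bod[b, "cy"], bod[b, "cx"], bod[b, "ry"],
                          bod[b, "rx"], bod[b, "theta"], bod[b, "amp"],
                          cfg$edge_sharpness)
          if (!is.null(p))
            img[p$r0:p$r1, p$c0:p$c1] <- img[p$r0:p$r1, p$c0:p$c1] + p$patch
        }
      out[, , f] <- img
    }
    out
  }
  arr[, , , 1] <- render_channel(bodies_by_frame)
  if (nch == 2L) arr[, , , 2] <- render_channel(ca_by_frame)

  if (noise) {
    n <- h * w * nf
    for (ch in seq_len(nch)) {
      set.seed(derive_seed(cfg$seed, 10^6 + ch))
      v <- cfg$photon_scale * rpois(n, arr[, , , ch] / cfg$photon_scale)
      v <- v + rnorm(n, 0, cfg$read_noise_sd)
      v[v < 0] <- 0
      arr[, , , ch] <- v
    }
  }

  cells_tbl <- if (cfg$n_cells > 0) bind_rows(cells) else
    tibble(cell_id = integer(), expelled = logical(), apoptotic = logical(),
           condensation_onset = integer(), expulsion_onset = integer(),
           calcium_spike_frame = integer(), baseline_area = double(),
           row0 = double(), col0 = double())
  truth_tbl <- if (cfg$n_cells > 0) bind_rows(truth_rows) else
    tibble(cell_id = integer(), frame = integer(), row = double(),
           col = double(), area = double())

  structure(list(
    movie = movie_stack(arr,
                        channel_names = c("nuclear", "calcium")[seq_len(nch)],
                        frame_interval = cfg$frame_interval,
                        pixel_size = cfg$pixel_size),
    cells = cells_tbl, truth = truth_tbl, config = cfg),
    class = "nucexpel_sim")
}

#' @export
print.nucexpel_sim <- function(x, ...) {
  cat("<nucexpel_sim>\n")
  print(x$movie)
  cat(sprintf("  %d cells (%d apoptotic, %d expelled), seed %d\n",
              nrow(x$cells), sum(x$cells$apoptotic), sum(x$cells$expelled),
              x$config$seed))
  invisible(x)
}
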