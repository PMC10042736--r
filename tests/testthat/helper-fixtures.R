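# Programmatic fixtures: small configurations and hand-built frames.

# A compact movie configuration that still exercises the full phenotype.
small_config <- function(...) {
  args <- list(
    n_cells = 9, frame_height = 160, frame_width = 160, n_frames = 30,
    fraction_apoptotic = 1, fraction_expelling = 1,
    condensation_onset_range = c(8, 12), expulsion_delay_range = c(4, 6),
    seed = 1)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# Tiny calcium-enabled configuration (16-cell field).
calcium_config <- function(lead = 8, seed = 1, ...) {
  small_config(n_cells = 16, frame_height = 170, frame_width = 170,
               n_frames = 44, calcium_enabled = TRUE,
               condensation_onset_range = c(18, 22),
               expulsion_delay_range = c(4, 6),
               calcium_spike_lead = lead, fragmentation_prob = 0.2,
               seed = seed, ...)
}

# Build a labeled_frame directly from centroids and areas (unit "masks" are
# not rendered; label images get one pixel per region, enough for tracking).
make_lf <- function(frame, row, col, area, h = 64, w = 64,
                    mean_extra = NULL) {
  labels <- matrix(0L, h, w)
  n <- length(row)
  for (k in seq_len(n))
    labels[max(1, round(row[k]) + 1), max(1, round(col[k]) + 1)] <- k
  regions <- tibble::tibble(label = seq_len(n), row = row, col = col,
                            area = area, peak = rep(1, n))
  if (!is.null(mean_extra))
    for (nm in names(mean_extra)) regions[[nm]] <- mean_extra[[nm]]
  structure(list(frame = frame, labels = labels, regions = regions,
                 threshold = NA_real_, background = NA_real_),
            class = "labeled_frame")
}

# Render one smooth-edged blob the way the simulator does (logistic edge),
# for segmentation tests that need a known ground-truth area.
test_blob_image <- function(h, w, cy, cx, r, amp = 1000, bg = 100, s = 0.1) {
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  rho <- sqrt(yy^2 + xx^2) / r
  bg + amp / (1 + exp((rho - 1) / s))
}
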