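#' Configuration for a synthetic nuclear-expulsion movie
#'
#' Builds and validates the parameter set for [simulate_movie()]. The
#' simulator renders a single field of view, single z-plane movie of nuclei
#' (an H2B reporter channel, optionally a calcium-indicator channel) in which
#' a configurable fraction of cells undergoes apoptosis (chromatin
#' condensation, optional fragmentation into apoptotic bodies) and a subset of
#' those additionally undergoes nuclear expulsion: a rapid, monotone increase
#' of chromatin area to `expansion_fold` times its baseline, with the total
#' integrated chromatin intensity conserved (the signal dilutes as it
#' spreads).
#'
#' Cells are placed on a jittered grid with spacing `5 * baseline_radius_mean`
#' pixels so that nuclei stay resolvable; the frame must be large enough to
#' hold `n_cells` grid positions. There is no cell division, birth, or
#' photobleaching.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Acquisition interval in minutes (metadata only).
#' @param n_cells Number of cells to place (>= 0).
#' @param fraction_expelling Proportion of cells that undergo nuclear
#'   expulsion. Expelling cells are a subset of apoptotic cells, so
#'   `fraction_expelling <= fraction_apoptotic`.
#' @param fraction_apoptotic Proportion of cells that die (condense, possibly
#'   fragment).
#' @param baseline_radius_mean,baseline_radius_sd Baseline nuclear equivalent
#'   radius (pixels); per-cell radii are drawn from a normal distribution and
#'   truncated at 3 px.
#' @param expansion_fold Target area fold-change at full expansion (> 1).
#' @param expansion_duration Frames over which the expansion ramps up.
#' @param condensation_fold Area shrinkage factor during apoptotic
#'   condensation (< 1).
#' @param condensation_duration Frames over which condensation proceeds.
#' @param condensation_onset_range Inclusive frame range (0-based) from which
#'   each apoptotic cell's condensation onset is drawn uniformly.
#' @param expulsion_delay_range Inclusive range of frames between condensation
#'   onset and expulsion onset for expelling cells.
#' @param fragmentation_prob Probability that an apoptotic cell fragments into
#'   2--4 apoptotic bodies after condensation.
#' @param drift_sd Per-frame random-walk drift of each cell centroid
#'   (pixels/frame, per axis).
#' @param background_level Background intensity (counts).
#' @param photon_scale Gain of the Poisson photon-noise model: pixel counts
#'   are `photon_scale * Poisson(expected / photon_scale)`.
#' @param read_noise_sd Gaussian read noise s.d. (counts).
#' @param nuclear_amp_mean,nuclear_amp_sd Peak nuclear intensity above
#'   background at baseline (counts); per-cell, truncated at 300.
#' @param edge_sharpness Relative width of the logistic edge of each rendered
#'   nucleus (fraction of its radius). Nuclei are anisotropic smooth-edged
#'   elliptical blobs: flat core, sigmoidal falloff, so that the area enclosed
#'   by the half-maximum contour equals the ground-truth ellipse area.
#' @param area_jitter_sd S.d. of per-frame lognormal jitter of baseline area.
#' @param aspect_sd S.d. of the log nuclear aspect ratio.
#' @param calcium_enabled Render a second (calcium indicator) channel?
#' @param calcium_amp Baseline calcium intensity above background inside the
#'   cell (counts).
#' @param calcium_spike_lead Frames by which the calcium spike precedes
#'   expulsion onset.
#' @param calcium_spike_fold Fold-increase of calcium intensity during the
#'   spike (sustained from the spike frame onwards).
#' @param cell_spacing Grid pitch for cell placement, in multiples of
#'   `baseline_radius_mean`. The default (5) gives realistic monolayer
#'   crowding in which fully expanded neighbours can touch; raise it for
#'   deliberately well-separated validation movies.
#' @param pixel_size Optional physical pixel size in micrometres (metadata).
#' @param seed Integer master seed. All per-cell parameters are drawn from
#'   per-cell substreams derived from it by counter, so adding cells does not
#'   perturb the realisations of earlier cells.
#'
#' @return A `simulation_config` object (a validated named list).
#' @seealso [simulate_movie()]
#' @export
#' @examples
#' cfg <- simulation_config(n_cells = 4, frame_height = 160, frame_width = 160,
#'                          n_frames = 30, fraction_apoptotic = 1,
#'                          fraction_expelling = 1, seed = 7)
#' cfg$expansion_fold
simulation_config <- function(frame_height = 480, frame_width = 480,
                              n_frames = 48, frame_interval = 3,
                              n_cells = 100,
                              fraction_expelling = 0, fraction_apoptotic = 0,
                              baseline_radius_mean = 8, baseline_radius_sd = 1,
                              expansion_fold = 3, expansion_duration = 6,
                              condensation_fold = 0.6,
                              condensation_duration = 3,
                              condensation_onset_range = c(15, 25),
                              expulsion_delay_range = c(4, 8),
                              fragmentation_prob = 0.3,
                              drift_sd = 0.3,
                              background_level = 100, photon_scale = 1,
                              read_noise_sd = 5,
                              nuclear_amp_mean = 1500, nuclear_amp_sd = 200,
                              edge_sharpness = 0.1,
                              area_jitter_sd = 0.03, aspect_sd = 0.12,
                              calcium_enabled = FALSE, calcium_amp = 600,
                              calcium_spike_lead = 8, calcium_spike_fold = 3,
                              cell_spacing = 5, pixel_size = NULL, seed = 1L) {
  cfg <- list(
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    n_cells = as.integer(n_cells),
    fraction_expelling = fraction_expelling,
    fraction_apoptotic = fraction_apoptotic,
    baseline_radius_mean = baseline_radius_mean,
    baseline_radius_sd = baseline_radius_sd,
    expansion_fold = expansion_fold,
    expansion_duration = as.integer(expansion_duration),
    condensation_fold = condensation_fold,
    condensation_duration = as.integer(condensation_duration),
    condensation_onset_range = as.integer(condensation_onset_range),
    expulsion_delay_range = as.integer(expulsion_delay_range),
    fragmentation_prob = fragmentation_prob,
    drift_sd = drift_sd,
    background_level = background_level,
    photon_scale = photon_scale,
    read_noise_sd = read_noise_sd,
    nuclear_amp_mean = nuclear_amp_mean,
    nuclear_amp_sd = nuclear_amp_sd,
    edge_sharpness = edge_sharpness,
    area_jitter_sd = area_jitter_sd,
    aspect_sd = aspect_sd,
    calcium_enabled = isTRUE(calcium_enabled),
    calcium_amp = calcium_amp,
    calcium_spike_lead = as.integer(calcium_spike_lead),
    calcium_spike_fold = calcium_spike_fold,
    cell_spacing = cell_spacing,
    pixel_size = pixel_size,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  fail <- function(inv) {
    abort(paste0("invalid simulation config: violated invariant '", inv, "'"),
          class = "nucexpel_config_error")
  }
  with(cfg, {
    if (!(fraction_expelling >= 0 && fraction_expelling <= fraction_apoptotic &&
          fraction_apoptotic <= 1))
      fail("0 <= fraction_expelling <= fraction_apoptotic <= 1")
    if (n_frames < 2) fail("n_frames >= 2")
    if (n_cells < 0) fail("n_cells >= 0")
    if (!(baseline_radius_mean > 0 && baseline_radius_sd >= 0 &&
          photon_scale > 0 && nuclear_amp_mean > 0 && background_level >= 0 &&
          calcium_amp > 0 && edge_sharpness > 0))
      fail("all radii, folds, scales > 0")
    if (expansion_fold <= 1) fail("expansion_fold > 1")
    if (!(condensation_fold > 0 && condensation_fold < 1))
      fail("0 < condensation_fold < 1")
    if (fragmentation_prob < 0 || fragmentation_prob > 1)
      fail("0 <= fragmentation_prob <= 1")
    if (frame_height < 8 || frame_width < 8) fail("frame at least 8x8 pixels")
    if (read_noise_sd < 0 || drift_sd < 0) fail("noise and drift sds >= 0")
    if (calcium_spike_fold <= 0) fail("calcium_spike_fold > 0")
    if (cell_spacing < 3) fail("cell_spacing >= 3")
  })
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  frame: %d x %d px, %d frames @ %g min\n",
              x$frame_height, x$frame_width, x$n_frames, x$frame_interval))
  cat(sprintf("  cells: %d (apoptotic %.2f, expelling %.2f)\n",
              x$n_cells, x$fraction_apoptotic, x$fraction_expelling))
  cat(sprintf("  expansion: %gx over %d frames; condensation %gx; calcium %s\n",
              x$expansion_fold, x$expansion_duration, x$condensation_fold,
              if (x$calcium_enabled) "on" else "off"))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# deterministic 32-bit substream seed for cell/stream `i` under master `seed`
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 1013904223 * (as.double(i) + 1)) %%
               2147483629)
}
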