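test_that("invalid configurations are rejected with the violated invariant", {
  expect_error(simulation_config(fraction_expelling = 0.9,
                                 fraction_apoptotic = 0.5),
               "fraction_expelling", class = "nucexpel_config_error")
  expect_error(simulation_config(n_frames = 1), "n_frames",
               class = "nucexpel_config_error")
  expect_error(simulation_config(expansion_fold = 0.9), "expansion_fold",
               class = "nucexpel_config_error")
  expect_error(simulation_config(condensation_fold = 1.4),
               "condensation_fold", class = "nucexpel_config_error")
  expect_error(simulate_movie(small_config(n_cells = 1000)),
               "frame too small", class = "nucexpel_config_error")
})

test_that("an empty movie is background and noise only", {
  cfg <- small_config(n_cells = 0, n_frames = 4)
  sim <- simulate_movie(cfg, noise = FALSE)
  expect_equal(nrow(sim$cells), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(sim$movie == cfg$background_level))
  noisy <- simulate_movie(cfg)
  # Poisson(background) + read noise: mean near background, variance near
  # background + read_noise_sd^2
  expect_lt(abs(mean(noisy$movie) - cfg$background_level), 1)
  expect_lt(abs(var(as.vector(noisy$movie)) -
                  (cfg$background_level + cfg$read_noise_sd^2)) /
              (cfg$background_level + cfg$read_noise_sd^2), 0.1)
})

test_that("all-expelling ground truth reaches expansion_fold by movie end", {
  cfg <- small_config(n_cells = 10, n_frames = 32, seed = 42)
  sim <- simulate_movie(cfg, noise = FALSE)
  expect_true(all(sim$cells$expelled))
  expect_true(all(sim$cells$apoptotic))
  per_cell <- split(sim$truth, sim$truth$cell_id)
  for (tr in per_cell) {
    baseline <- median(tr$area[tr$frame < min(cfg$condensation_onset_range)])
    ratio <- tr$area[which.max(tr$frame)] / baseline
    expect_lt(abs(ratio - cfg$expansion_fold) / cfg$expansion_fold, 0.1)
  }
})

test_that("ground-truth event ordering and calcium lead are consistent", {
  sim <- simulate_movie(calcium_config(lead = 8, seed = 3), noise = FALSE)
  cells <- sim$cells
  expect_true(all(cells$expulsion_onset[cells$expelled] >
                    cells$condensation_onset[cells$expelled]))
  expect_true(all(!cells$expelled | cells$apoptotic))
  expect_equal(cells$calcium_spike_frame[cells$expelled],
               cells$expulsion_onset[cells$expelled] - 8)
  expect_true(all(sim$truth$area > 0))
})

test_that("same config and seed give bit-identical movies and truth", {
  cfg <- small_config(seed = 5, calcium_enabled = TRUE)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(unclass(a$movie), unclass(b$movie))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
})

test_that("per-cell substreams: adding cells does not perturb earlier cells", {
  small <- simulate_movie(small_config(n_cells = 4, seed = 9), noise = FALSE)
  big <- simulate_movie(small_config(n_cells = 9, seed = 9), noise = FALSE)
  expect_identical(small$cells, big$cells[1:4, ])
  expect_identical(small$truth,
                   dplyr::filter(big$truth, cell_id <= 4))
})

test_that("realized expelled fraction matches the Bernoulli draw at n = 1000", {
  p <- 0.85
  cfg <- simulation_config(n_cells = 1000, frame_height = 1280,
                           frame_width = 1280, n_frames = 2,
                           condensation_onset_range = c(0, 1),
                           expulsion_delay_range = c(0, 1),
                           fraction_apoptotic = 1, fraction_expelling = p,
                           seed = 11)
  sim <- simulate_movie(cfg, noise = FALSE)
  k <- sum(sim$cells$expelled)
  expect_lt(abs(k - 1000 * p), 3 * sqrt(1000 * p * (1 - p)))
  # nested fates: every expelling cell is apoptotic
  expect_true(all(!sim$cells$expelled | sim$cells$apoptotic))
})

test_that("noiseless rendered mask recovers ground-truth area within 10%", {
  cfg <- small_config(n_cells = 4, fraction_apoptotic = 0,
                      fraction_expelling = 0,
                      baseline_radius_mean = 6, baseline_radius_sd = 0.5,
                      n_frames = 3, seed = 13)
  sim <- simulate_movie(cfg, noise = FALSE)
  img <- sim$movie[, , 1, 1]
  truth0 <- dplyr::filter(sim$truth, frame == 0)
  for (i in truth0$cell_id) {
    ctr <- truth0[truth0$cell_id == i, ]
    # isolate a window around the cell and integrate its half-max mask
    # +-12 px window holds the whole mask but no neighbour (grid pitch 30)
    rr <- round(ctr$row + 1) + (-12:12)
    cc <- round(ctr$col + 1) + (-12:12)
    rr <- rr[rr >= 1 & rr <= nrow(img)]
    cc <- cc[cc >= 1 & cc <= ncol(img)]
    win <- img[rr, cc]
    bg <- cfg$background_level
    mask_area <- sum(win > bg + 0.5 * (max(win) - bg))
    expect_lt(abs(mask_area - ctr$area) / ctr$area, 0.1)
  }
})

test_that("a simulation bundle writes movie, truth tables and config", {
  sim <- simulate_movie(small_config(n_cells = 2, n_frames = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(list.files(dir), c("movie.tif", "ground_truth.csv",
                                     "truth_frames.csv", "config.json"))
  gt <- readr::read_csv(file.path(dir, "ground_truth.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(gt), 2)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 1)
  frames <- segment_movie(sim$movie)
  p <- file.path(dir, "labels.tif")
  write_labels_tiff(frames, p)
  back <- tiff::readTIFF(p, all = TRUE)
  expect_equal(length(back), 3)
  expect_equal(round(back[[1]] * 65535), frames[[1]]$labels,
               ignore_attr = TRUE)
})

test_that("TIFF round-trip preserves integer counts and geometry", {
  sim <- simulate_movie(small_config(n_cells = 2, n_frames = 3,
                                     calcium_enabled = TRUE))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, path)
  back <- read_movie_tiff(path, n_channels = 2,
                          channel_names = c("nuclear", "calcium"))
  expect_equal(dim(back), dim(sim$movie))
  expect_equal(unclass(back)[, , , 1], round(unclass(sim$movie)[, , , 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
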