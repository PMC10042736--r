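#' Run the full analysis on one movie
#'
#' Convenience composition of the per-movie stages: segment every frame,
#' merge apoptotic fragments, track cells, baseline-normalize areas and
#' compute expulsion scores.
#'
#' @param movie A [movie_stack()] or a `nucexpel_sim` (its movie is used).
#' @param baseline_window Inclusive 0-based frame range for baselines.
#' @param intervals Gradient interval widths (frames) for the score.
#' @param max_link_distance,max_gap Tracking parameters ([track_cells()]).
#' @param keep_frames Keep the per-frame label images in the result? They are
#'   needed later for calcium measurement but are large.
#' @inheritParams segment_movie
#' @inheritDotParams segment_frame -image -channels -frame
#' @return List: `traces`, `expansion` (with `excluded` attribute), `scores`,
#'   and `frames` (if `keep_frames`).
#' @export
analyze_movie <- function(movie, baseline_window = c(0, 4),
                          intervals = c(1, 2, 4, 8), merge_radius = NULL,
                          max_link_distance = 15, max_gap = 2,
                          keep_frames = FALSE, ...) {
  if (inherits(movie, "nucexpel_sim")) movie <- movie$movie
  frames <- segment_movie(movie, merge_radius = merge_radius, ...)
  traces <- track_cells(frames, max_link_distance = max_link_distance,
                        max_gap = max_gap)
  expansion <- normalize_traces(traces, baseline_window = baseline_window)
  scores <- expulsion_scores(expansion, intervals = intervals)
  out <- list(traces = traces, expansion = expansion, scores = scores)
  if (keep_frames) out$frames <- frames
  out
}

#' Simulate and score a cohort of cells across fields of view
#'
#' Simulates `n_cells` cells of one condition, split across fields of
#' `cells_per_field` cells each (each field an independent movie with a seed
#' derived from `seed` by field counter), runs the full per-movie analysis,
#' and returns pooled per-cell scores with globally unique cell ids.
#'
#' Conditions follow the calibration design of the assay: a
#' `"positive"`-like cohort has all cells apoptotic with a high expelling
#' fraction; a `"negative"`-like cohort undergoes apoptosis (condensation,
#' fragmentation) with zero true expulsion.
#'
#' @param n_cells Total cells to simulate.
#' @param condition Label attached to the returned scores.
#' @param seed Master seed for the cohort.
#' @param fraction_apoptotic,fraction_expelling Fate fractions (see
#'   [simulation_config()]).
#' @param cells_per_field Cells per simulated field of view (default 144 fills
#'   the placement grid of the default 480 x 480 frame).
#' @param config_args Extra arguments passed to [simulation_config()].
#' @param analysis_args Extra arguments passed to [analyze_movie()].
#' @return List: `scores` (pooled tibble with `condition` and per-field
#'   provenance), `expansion` (pooled expansion traces with `condition`),
#'   `truth` (pooled per-cell ground truth), `n_fields`.
#' @export
simulate_cohort <- function(n_cells, condition = "positive", seed = 1,
                            fraction_apoptotic = 1, fraction_expelling = 0.85,
                            cells_per_field = 144, config_args = list(),
                            analysis_args = list()) {
  n_fields <- ceiling(n_cells / cells_per_field)
  left <- n_cells
  scores <- list(); expansion <- list(); truth <- list()
  offset <- 0L
  for (fld in seq_len(n_fields)) {
    nc <- min(cells_per_field, left)
    left <- left - nc
    cfg <- do.call(simulation_config, c(list(
      n_cells = nc, fraction_apoptotic = fraction_apoptotic,
      fraction_expelling = fraction_expelling,
      seed = derive_seed(seed, 5000 + fld)), config_args))
    sim <- simulate_movie(cfg)
    res <- do.call(analyze_movie, c(list(sim$movie), analysis_args))
    scores[[fld]] <- res$scores %>%
      mutate(cell_id = .data$cell_id + offset, condition = condition,
             field = fld)
    expansion[[fld]] <- res$expansion %>%
      mutate(cell_id = .data$cell_id + offset, condition = condition)
    truth[[fld]] <- sim$cells %>%
      mutate(sim_cell_id = .data$cell_id, field = fld,
             condition = condition)
    offset <- offset + max(res$scores$cell_id, 0L)
  }
  list(scores = bind_rows(scores), expansion = bind_rows(expansion),
       truth = bind_rows(truth), n_fields = n_fields)
}

#' Calibrated wild-type/knockout benchmark
#'
#' Simulates a paired positive-condition (wild-type-like, true expelling
#' fraction `fraction_expelling`) and negative-condition (knockout-like, no
#' true expulsion) cohort, calibrates a score threshold by ROC between them,
#' classifies both cohorts, and reports percent expulsion per condition.
#' This mirrors the assay's calibration: whole conditions define the ROC
#' classes, wild-type positive and knockout negative.
#'
#' @inheritParams simulate_cohort
#' @param method Threshold rule for [select_threshold()].
#' @param alpha FPR bound when `method = "fixed_fpr"`.
#' @return List: `roc` (`expulsion_roc` with chosen threshold), `threshold`,
#'   `result` (`expulsion_result`), `scores` (pooled tibble, conditions
#'   `"WT"` and `"KO"`), `expansion`, `truth`.
#' @export
run_benchmark <- function(n_cells = 2000, seed = 1, fraction_expelling = 0.85,
                          cells_per_field = 144, method = "youden",
                          alpha = NULL, config_args = list(),
                          analysis_args = list()) {
  wt <- simulate_cohort(n_cells, condition = "WT", seed = derive_seed(seed, 1),
                        fraction_apoptotic = 1,
                        fraction_expelling = fraction_expelling,
                        cells_per_field = cells_per_field,
                        config_args = config_args,
                        analysis_args = analysis_args)
  ko <- simulate_cohort(n_cells, condition = "KO", seed = derive_seed(seed, 2),
                        fraction_apoptotic = 1, fraction_expelling = 0,
                        cells_per_field = cells_per_field,
                        config_args = config_args,
                        analysis_args = analysis_args)
  scores <- bind_rows(wt$scores, ko$scores)
  pos <- scores$score[scores$condition == "WT" & !scores$unscorable]
  neg <- scores$score[scores$condition == "KO" & !scores$unscorable]
  roc <- build_roc(pos, neg)
  threshold <- select_threshold(roc, method = method, alpha = alpha)
  roc$chosen_threshold <- threshold
  roc$selection_method <- method
  result <- classify_and_summarize(scores, threshold)
  list(roc = roc, threshold = threshold, result = result, scores = scores,
       expansion = bind_rows(wt$expansion, ko$expansion),
       truth = bind_rows(wt$truth, ko$truth))
}

#' Figure-style summary tables from scored results
#'
#' Builds the three headline summaries of an expulsion experiment: a
#' histogram of per-cell maximum chromatin expansion, per-condition median
#' expansion curves over time, and percent expulsion per condition.
#'
#' @param expansion Pooled expansion tibble with a `condition` column.
#' @param scores Pooled score tibble.
#' @param result An `expulsion_result`.
#' @param hist_breaks Histogram bin edges for maximum expansion.
#' @return List of tibbles: `histogram` (`condition`, `bin_low`, `bin_high`,
#'   `n`), `median_curves` (`condition`, `frame`, `median_e`, `n`),
#'   `percent` (per-condition summary).
#' @export
render_summary <- function(expansion, scores, result,
                           hist_breaks = seq(0, 8, by = 0.25)) {
  stopifnot("condition" %in% names(expansion))
  max_e <- expansion %>%
    group_by(.data$condition, .data$cell_id) %>%
    summarise(max_e = max(.data$e), .groups = "drop")
  brk <- c(hist_breaks, Inf)
  histogram <- max_e %>%
    mutate(bin = cut(.data$max_e, breaks = brk, right = FALSE)) %>%
    count(.data$condition, .data$bin, .drop = FALSE) %>%
    mutate(bin_low = brk[as.integer(.data$bin)],
           bin_high = brk[as.integer(.data$bin) + 1L]) %>%
    select("condition", "bin_low", "bin_high", "n")
  median_curves <- expansion %>%
    group_by(.data$condition, .data$frame) %>%
    summarise(median_e = median(.data$e), n = dplyr::n(), .groups = "drop")
  list(histogram = histogram, median_curves = median_curves,
       percent = result$summary)
}

#' Run the end-to-end pipeline from a single configuration
#'
#' Orchestrates simulate -> segment/track -> score -> calibrate (-> calcium)
#' -> report from one configuration list, writes every artifact under
#' `out_dir`, and returns a manifest listing each file with its MD5 content
#' hash, the seed, and the resolved parameters. All randomness derives from
#' `config$seed`, so identical configurations reproduce identical artifacts
#' and hashes.
#'
#' @param config A list with elements:
#'   * `seed`: integer master seed (required);
#'   * `conditions`: named list of condition specs, each a list with
#'     `n_cells`, `fraction_apoptotic`, `fraction_expelling`, and optional
#'     `config_args` for [simulation_config()];
#'   * `calibrate`: optional list `positive`, `negative` (condition names),
#'     `method`, `alpha`;
#'   * `calcium`: optional list `enabled`, `spike_fold`, `min_run`,
#'     `condition` (which condition to measure; its `config_args` must set
#'     `calcium_enabled = TRUE`);
#'   * `analysis`: optional arguments for [analyze_movie()];
#'   * `cells_per_field`: cells per simulated field (default 100).
#' @param out_dir Output directory (created if needed).
#' @return The manifest (a list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed)) abort("run_pipeline: config$seed is required")
  if (is.null(config$conditions) || !length(config$conditions))
    abort("run_pipeline: config$conditions is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analysis_args <- config$analysis %||% list()
  cpf <- config$cells_per_field %||% 144
  files <- character()

  put_csv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    files[[length(files) + 1L]] <<- p
  }
  put_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    files[[length(files) + 1L]] <<- p
  }

  cohorts <- list()
  for (nm in names(config$conditions)) {
    cc <- config$conditions[[nm]]
    cohorts[[nm]] <- simulate_cohort(
      n_cells = cc$n_cells,
      condition = nm,
      seed = derive_seed(config$seed, match(nm, names(config$conditions))),
      fraction_apoptotic = cc$fraction_apoptotic %||% 1,
      fraction_expelling = cc$fraction_expelling %||% 0,
      cells_per_field = cpf,
      config_args = cc$config_args %||% list(),
      analysis_args = analysis_args)
  }
  scores <- bind_rows(lapply(cohorts, `[[`, "scores"))
  expansion <- bind_rows(lapply(cohorts, `[[`, "expansion"))
  put_csv(scores, "scores.csv")

  summary_out <- list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("nucexpel")))
  result <- NULL
  if (!is.null(config$calibrate)) {
    cal <- config$calibrate
    pos <- scores %>% filter(.data$condition == cal$positive,
                             !.data$unscorable)
    neg <- scores %>% filter(.data$condition == cal$negative,
                             !.data$unscorable)
    roc <- build_roc(pos$score, neg$score)
    threshold <- select_threshold(roc, method = cal$method %||% "youden",
                                  alpha = cal$alpha)
    roc$chosen_threshold <- threshold
    roc$selection_method <- cal$method %||% "youden"
    result <- classify_and_summarize(scores, threshold)
    put_csv(tidy(roc), "roc.csv")
    put_csv(result$summary, "summary.csv")
    summary_out$auc <- roc$auc
    summary_out$threshold <- threshold
    summary_out$threshold_rule <- roc$selection_method
    summary_out$percent_expulsion <- setNames(
      as.list(result$summary$percent_expulsion), result$summary$condition)
    rep_tabs <- render_summary(expansion, scores, result)
    put_csv(rep_tabs$histogram, "expansion_histogram.csv")
    put_csv(rep_tabs$median_curves, "median_expansion.csv")
  }
  if (isTRUE(config$calcium$enabled)) {
    ca_cfg <- config$calcium
    nm <- ca_cfg$condition %||% names(config$conditions)[1]
    cc <- config$conditions[[nm]]
    cfg_args <- cc$config_args %||% list()
    cfg_args$calcium_enabled <- TRUE
    cfg <- do.call(simulation_config, c(list(
      n_cells = min(cc$n_cells, cpf),
      fraction_apoptotic = cc$fraction_apoptotic %||% 1,
      fraction_expelling = cc$fraction_expelling %||% 0,
      seed = derive_seed(config$seed, 9000)), cfg_args))
    sim <- simulate_movie(cfg)
    res <- do.call(analyze_movie, c(list(sim$movie, keep_frames = TRUE),
                                    analysis_args))
    ca <- measure_calcium(sim$movie, res$frames, res$traces)
    spikes <- detect_spikes(ca, spike_fold = ca_cfg$spike_fold %||% 1.5,
                            min_run = ca_cfg$min_run %||% 2)
    lag <- spike_expulsion_lag(spikes, res$scores)
    put_csv(ca, "calcium_traces.csv")
    put_csv(lag$per_cell, "calcium_lags.csv")
    summary_out$calcium <- as.list(lag$summary)
  }
  put_json(summary_out, "summary.json")

  manifest <- list(
    seed = config$seed,
    package = "nucexpel",
    version = as.character(utils::packageVersion("nucexpel")),
    parameters = config[setdiff(names(config), "seed")],
    artifacts = lapply(files, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
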