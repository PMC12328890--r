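# Pipeline orchestration: configuration, staged commands, manifest.
#
# Every stage is a plain function over files in an output directory, fully
# determined by the configuration and the seed; the manifest records config
# and output hashes so a re-run can be verified byte-for-byte.

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "larkin_out",
    omission = "counts",
    acquisition = list(),                 # overrides for acquisition_spec()
    video = list(enabled = FALSE, duration_ms = 1200,
                 lx_amplitude_mm = 5, lx_onset_ms = 300,
                 lx_transition_ms = 300, lx_hold_ms = 150,
                 lx_release_ms = 300, noise_sd = 0.01),
    vtr = list(label = "LX", top = 41, left = 35, height = 17, width = 6),
    seed_point = list(row = 50, col = 38),
    roi = list(label = "LAB", center_row = 30, center_col = 60,
               radius_px = 3),
    smoothing = list(h = 0.9, h_units = "frames", span_points = 30),
    landmarks = list(threshold = 0.2, noise_floor = 0.05),
    stats = list(alpha = 0.05,
                 measures = c("lx_displacement_mm", "onset_lag_ms",
                              "target_lag_ms"))
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unset fields with package
#' defaults, and validates the result. A run is reproducible from the
#' configuration and its seed alone.
#'
#' @param config path to a YAML file, a list of overrides, or `NULL` for
#'   the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config %||% list())
  if (!is.numeric(cfg$seed)) stopf("config field 'seed' must be numeric")
  if (!is.character(cfg$out_dir)) stopf("config field 'out_dir' must be a path")
  cfg$omission <- match.arg(cfg$omission, c("counts", "bernoulli"))
  class(cfg) <- "pipeline_config"
  cfg
}

config_acq <- function(cfg) do.call(acquisition_spec, cfg$acquisition)

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, stage, files, counts = list()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else
    list(config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("larkin")),
         stages = list())
  manifest$stages[[stage]] <- list(
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate stage: token tables and optional phantom videos
#'
#' Writes `tokens.csv` (one row per token across all speakers) and, when
#' `config$video$enabled`, a phantom TIFF stack plus its ground-truth CSV.
#' Updates the run manifest.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @return invisible list of written paths.
#' @export
run_simulate <- function(config = NULL) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tokens <- generate_study_tokens(seed = cfg$seed, omission = cfg$omission)
  tok_path <- file.path(cfg$out_dir, "tokens.csv")
  utils::write.csv(tokens, tok_path, row.names = FALSE)
  files <- tok_path
  counts <- list(tokens = nrow(tokens),
                 tokens_per_speaker = nrow(tokens) /
                   length(unique(tokens$speaker)),
                 omitted = sum(tokens$omitted))
  if (isTRUE(cfg$video$enabled)) {
    acq <- config_acq(cfg)
    vc <- cfg$video
    scene <- phantom_scene(
      larynx_blob = phantom_blob(x_px = cfg$seed_point$col,
                                 y_px = cfg$seed_point$row),
      larynx_gesture = gesture_spec(vc$lx_onset_ms, vc$lx_transition_ms,
                                    vc$lx_hold_ms, vc$lx_release_ms,
                                    vc$lx_amplitude_mm),
      noise_sd = vc$noise_sd)
    ph <- render_phantom_video(scene, acq, vc$duration_ms, seed = cfg$seed)
    vid_path <- file.path(cfg$out_dir, "phantom.tiff")
    gt_path <- file.path(cfg$out_dir, "ground_truth.csv")
    write_video_tiff(ph$video, vid_path)
    utils::write.csv(ph$ground_truth, gt_path, row.names = FALSE)
    files <- c(files, vid_path, gt_path)
  }
  write_manifest(cfg, "simulate", files, counts)
  invisible(list(files = files, tokens = tokens))
}

#' Track stage: centroid tracks from phantom videos
#'
#' Reads the simulate stage's TIFF, tracks the seeded object inside the
#' configured VTR, applies the local quadratic smoothing, and writes
#' `track.csv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible path of the track CSV.
#' @export
run_track <- function(config = NULL) {
  cfg <- pipeline_config(config)
  vid_path <- file.path(cfg$out_dir, "phantom.tiff")
  if (!file.exists(vid_path))
    stopf("no phantom video at '%s'; run run_simulate() with video enabled",
          vid_path)
  acq <- config_acq(cfg)
  video <- read_video_tiff(vid_path, acq)
  vtr <- vtr_spec(cfg$vtr$label, cfg$vtr$top, cfg$vtr$left,
                  cfg$vtr$height, cfg$vtr$width, acq)
  track <- track_centroids(video, vtr, cfg$seed_point$row, cfg$seed_point$col)
  track <- smooth_local_quadratic(track, cfg$smoothing$span_points)
  path <- file.path(cfg$out_dir, "track.csv")
  utils::write.csv(track, path, row.names = FALSE)
  write_manifest(cfg, "track", path,
                 list(frames = nrow(track), valid = sum(track$valid)))
  invisible(path)
}

#' Measure stage: landmarks and kinematic measures from a track
#'
#' Detects velocity-threshold landmarks on the smoothed vertical track
#' (direction chosen by the sign of the configured amplitude) and writes
#' `landmarks.csv` and `measures.csv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of written paths.
#' @export
run_measure <- function(config = NULL) {
  cfg <- pipeline_config(config)
  tr_path <- file.path(cfg$out_dir, "track.csv")
  if (!file.exists(tr_path)) stopf("no track at '%s'; run run_track()", tr_path)
  track <- utils::read.csv(tr_path)
  dir <- if ((cfg$video$lx_amplitude_mm %||% 1) >= 0) "raising" else "lowering"
  lm <- find_gesture_landmarks(track$vertical_mm, track$time_ms,
                               threshold = cfg$landmarks$threshold,
                               direction = dir,
                               noise_floor = cfg$landmarks$noise_floor)
  meas <- derive_measures(lm)
  lm_path <- file.path(cfg$out_dir, "landmarks.csv")
  ms_path <- file.path(cfg$out_dir, "measures.csv")
  utils::write.csv(cbind(landmark = rownames(lm), lm), lm_path,
                   row.names = FALSE)
  utils::write.csv(meas, ms_path, row.names = FALSE)
  write_manifest(cfg, "measure", c(lm_path, ms_path),
                 list(landmarks_found = sum(lm$found)))
  invisible(list(landmarks = lm_path, measures = ms_path))
}

#' Stats stage: grouped summaries and variability tests
#'
#' Applies the token-omission rule to `tokens.csv`, then writes per-measure
#' grouped summary CSVs (speaker x class cells plus count-weighted Totals),
#' Brown-Forsythe and CV-equality results for onset and target lags
#' (pulmonic vs non-pulmonic and ejective vs implosive contrasts), and
#' lag-duration correlations, as `summary_<measure>.csv`,
#' `variance_tests.json`, and `correlations.csv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of written paths.
#' @export
run_stats <- function(config = NULL) {
  cfg <- pipeline_config(config)
  tok_path <- file.path(cfg$out_dir, "tokens.csv")
  if (!file.exists(tok_path)) stopf("no tokens at '%s'; run run_simulate()",
                                    tok_path)
  tokens <- utils::read.csv(tok_path)
  kept <- apply_omission_rule(tokens)$retained
  files <- character(0)
  for (m in cfg$stats$measures) {
    gs <- group_summary(kept, m)
    p <- file.path(cfg$out_dir, sprintf("summary_%s.csv", m))
    utils::write.csv(gs, p, row.names = FALSE)
    files <- c(files, p)
  }
  lag_classes <- c("voiceless_ejective", "voiced_implosive", "voiced_pulmonic")
  tests <- list()
  for (m in c("onset_lag_ms", "target_lag_ms")) {
    x <- kept[kept$class %in% lag_classes & !is.na(kept[[m]]), ]
    pulm <- split(x[[m]], ifelse(x$class == "voiced_pulmonic",
                                 "pulmonic", "non_pulmonic"))
    ei <- split(x[[m]][x$class != "voiced_pulmonic"],
                x$class[x$class != "voiced_pulmonic"])
    bf1 <- brown_forsythe(pulm)
    bf2 <- brown_forsythe(ei)
    cv1 <- cv_equality_test(pulm)
    tests[[m]] <- list(
      brown_forsythe_pulmonic_vs_nonpulmonic =
        bf1[c("statistic", "df1", "df2", "p.value")],
      brown_forsythe_ejective_vs_implosive =
        bf2[c("statistic", "df1", "df2", "p.value")],
      cv_equality_pulmonic_vs_nonpulmonic =
        cv1[c("statistic", "df", "p.value")],
      alpha = cfg$stats$alpha)
  }
  tst_path <- file.path(cfg$out_dir, "variance_tests.json")
  jsonlite::write_json(tests, tst_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  corr <- lag_duration_correlation(
    kept[kept$class %in% c("voiced_implosive", "voiced_pulmonic"), ])
  cor_path <- file.path(cfg$out_dir, "correlations.csv")
  utils::write.csv(corr, cor_path, row.names = FALSE)
  files <- c(files, tst_path, cor_path)
  write_manifest(cfg, "stats", files,
                 list(tokens_in = nrow(tokens), tokens_retained = nrow(kept)))
  invisible(files)
}

#' Run the full token-level pipeline
#'
#' `run_simulate()` then `run_stats()`, plus the video stages
#' (`run_track()`, `run_measure()`) when the configuration enables the
#' phantom video.
#'
#' @param config a [pipeline_config()].
#' @return invisible path of the run manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  run_simulate(cfg)
  if (isTRUE(cfg$video$enabled)) {
    run_track(cfg)
    run_measure(cfg)
  }
  run_stats(cfg)
  invisible(file.path(cfg$out_dir, "manifest.json"))
}
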