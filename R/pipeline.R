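pipeline_defaults <- function() {
  list(
    seed = 42,
    synth = list(enabled = TRUE, n_seizure = 94, n_background = 94,
                 duration_min_s = 5, duration_max_s = 20,
                 fs = 256, n_channels = 19, swd_rate_hz = 3,
                 n_harmonics = 20, harmonic_decay = 0.85,
                 envelope_bw_hz = 0.5, background_slope = 1.5,
                 alpha_peak_hz = 10, snr = 3),
    input = list(dir = NULL, annotations = NULL, unmixing = NULL,
                 ic_probabilities = NULL),
    preprocess = list(line_hz = 60, notch_harmonics = 2, bandwidth_hz = 2),
    ic_select = list(combine = "or", nonartifact = "max"),
    cfc = list(f_min = 2, f_max = 120, n_freqs = 100, window_s = 2,
               overlap = 0.5, method = "pearson", min_windows = 8),
    ssae = list(hidden1 = 100, hidden2 = 50, sparsity_target = 0.10,
                sparsity_weight = 1, l2_weight = 1e-5, max_iter = 400,
                tol = 1e-8, fine_tune = TRUE, fine_tune_iter = 100,
                optimizer = "lbfgs", scaling = "fixed",
                fraction = 0.5, n_splits = 10),
    out_dir = NULL
  )
}

#' Build and validate a pipeline configuration
#'
#' Nested configuration for the end-to-end detector: `synth` (the synthetic
#' generator, or `input` paths for on-disk data), `preprocess`, `ic_select`,
#' `cfc` and `ssae` sections plus a global `seed` from which each stage's
#' seed is derived by a fixed offset. Every field has a default; unknown
#' keys are rejected.
#'
#' @param ... named overrides; nested sections are given as named lists,
#'   e.g. `pipeline_config(cfc = list(n_freqs = 40))`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  merge_section <- function(base, over, path) {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown)) {
      stop_with("cfcdetect_config", "unknown configuration key: %s",
                paste0(path, unknown[1]))
    }
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge_section(base[[nm]], as.list(over[[nm]]),
                                    paste0(path, nm, "$"))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_section(defaults, over, "")
  if (isTRUE(cfg$synth$enabled) &&
      (cfg$synth$n_seizure < 1 || cfg$synth$n_background < 1)) {
    stop_with("cfcdetect_config", "configuration requests zero segments")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file of overrides with the same nesting.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

synth_config_from <- function(cfg) {
  s <- cfg$synth
  synth_config(fs = s$fs, n_channels = s$n_channels,
               swd_rate_hz = s$swd_rate_hz, n_harmonics = s$n_harmonics,
               harmonic_decay = s$harmonic_decay,
               envelope_bw_hz = s$envelope_bw_hz,
               background_slope = s$background_slope,
               alpha_peak_hz = s$alpha_peak_hz, snr = s$snr,
               seed = derive_seed(cfg$seed, 1))
}

#' Comodulogram features for a list of segments
#'
#' Runs the preprocessing chain (common average reference, notch filter,
#' component projection, probability-based component selection) and the
#' per-segment comodulogram on each segment, flattening the result into one
#' feature row per retained segment. Segments too short for the minimum
#' window count, or with no surviving component, are excluded and listed.
#'
#' @param segments list of [eeg_segment()].
#' @param config a [pipeline_config()].
#' @param unmixing an [unmixing_matrix()] or `NULL` for the identity
#'   (channels as components).
#' @param ic_probs an [ic_probability_table()] shared by all segments, or
#'   `NULL` for the all-brain stand-in.
#' @return list with `features` (matrix), `labels`, `segment_ids`,
#'   `durations_s`, `grid` and `exclusions` (data.frame).
#' @export
extract_features <- function(segments, config = pipeline_config(),
                             unmixing = NULL, ic_probs = NULL) {
  pc <- config$preprocess
  cc <- config$cfc
  grid <- make_grid(cc$f_min, cc$f_max, cc$n_freqs)
  rows <- list()
  labels <- character(0)
  ids <- character(0)
  durs <- numeric(0)
  excl <- list()
  for (seg in segments) {
    res <- tryCatch({
      seg2 <- common_average_reference(seg)
      seg2 <- suppressWarnings(
        notch_filter(seg2, line_hz = pc$line_hz,
                     n_harmonics = pc$notch_harmonics,
                     bandwidth_hz = pc$bandwidth_hz))
      W <- if (is.null(unmixing)) identity_unmixing(n_channels(seg2))
           else unmixing
      acts <- apply_unmixing(seg2, W)
      probs <- if (is.null(ic_probs)) iclabel_stand_in(nrow(acts$acts))
               else ic_probs
      mask <- select_good_ics(probs, combine = config$ic_select$combine,
                              nonartifact = config$ic_select$nonartifact)
      acts <- filter_activations(acts, mask)
      segment_cfc(acts, grid = grid, window_s = cc$window_s,
                  overlap = cc$overlap, method = cc$method,
                  min_windows = cc$min_windows)
    }, cfcdetect_too_short = function(e) e,
       cfcdetect_insufficient_data = function(e) e,
       cfcdetect_empty_selection = function(e) e)
    if (inherits(res, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        segment_id = seg$segment_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- flatten_cfc(res)
    labels <- c(labels, seg$label)
    ids <- c(ids, seg$segment_id)
    durs <- c(durs, duration_s(seg))
  }
  if (!length(rows)) {
    stop_with("cfcdetect_validation", "no segment survived feature extraction")
  }
  list(features = do.call(rbind, rows), labels = labels, segment_ids = ids,
       durations_s = durs, grid = grid,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(segment_id = character(0),
                                    reason = character(0)))
}

#' Run the full detection pipeline
#'
#' Simulate (or load) labelled segments, preprocess, select components,
#' compute per-segment comodulograms, then repeat a stratified half split
#' `n_splits` times: train the stacked sparse autoencoder on the train half,
#' classify the held-out half, and score it. Metrics are aggregated as
#' mean +/- sd over the splits. With a fixed seed the whole run is
#' deterministic. If `out_dir` is set, the resolved configuration, the
#' manifest, per-split metrics, the aggregate report, predictions of the
#' last split and a run log (exclusions) are written there.
#'
#' @param config a [pipeline_config()].
#' @return list with `metrics` (aggregate), `per_split`, `confusions`,
#'   `features`, `exclusions` and the resolved `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (isTRUE(config$synth$enabled)) {
    ds <- generate_dataset(config$synth$n_seizure, config$synth$n_background,
                           config = synth_config_from(config),
                           seed = derive_seed(config$seed, 2),
                           duration_range = c(config$synth$duration_min_s,
                                              config$synth$duration_max_s))
    segments <- ds$segments
    manifest <- ds$manifest
    unmixing <- NULL
    ic_probs <- NULL
  } else {
    if (is.null(config$input$dir)) {
      stop_with("cfcdetect_config",
                "synth disabled and no input directory given")
    }
    ds <- read_dataset(config$input$dir, fs = config$synth$fs)
    segments <- ds$segments
    manifest <- ds$manifest
    if (!is.null(config$input$annotations)) {
      ann <- read_annotations(config$input$annotations)
      segments <- unlist(lapply(segments, function(s) {
        if (s$segment_id %in% ann$segment_id) extract_intervals(s, ann)
        else list(s)
      }), recursive = FALSE)
    }
    unmixing <- if (!is.null(config$input$unmixing)) {
      read_unmixing(config$input$unmixing)
    }
    ic_probs <- if (!is.null(config$input$ic_probabilities)) {
      read_ic_probabilities(config$input$ic_probabilities)
    }
  }
  if (!length(segments)) {
    stop_with("cfcdetect_config", "configuration yields zero segments")
  }

  fx <- extract_features(segments, config, unmixing = unmixing,
                         ic_probs = ic_probs)
  if (length(unique(fx$labels)) < 2) {
    stop_with("cfcdetect_validation",
              "need both classes after feature extraction")
  }

  sc <- config$ssae
  tc <- train_config(hidden1 = sc$hidden1, hidden2 = sc$hidden2,
                     sparsity_target = sc$sparsity_target,
                     sparsity_weight = sc$sparsity_weight,
                     l2_weight = sc$l2_weight, max_iter = sc$max_iter,
                     tol = sc$tol, fine_tune = sc$fine_tune,
                     fine_tune_iter = sc$fine_tune_iter,
                     optimizer = sc$optimizer, scaling = sc$scaling,
                     seed = derive_seed(config$seed, 3))
  per_split <- vector("list", sc$n_splits)
  confusions <- vector("list", sc$n_splits)
  last_pred <- NULL
  for (s in seq_len(sc$n_splits)) {
    tc_s <- tc
    tc_s$seed <- derive_seed(config$seed, 100 + s)
    sp <- split_dataset(fx$labels, fraction = sc$fraction,
                        seed = derive_seed(config$seed, 200 + s))
    model <- train_ssae(fx$features[sp$train, , drop = FALSE],
                        fx$labels[sp$train], tc_s)
    pred <- predict(model, fx$features[sp$test, , drop = FALSE])
    cm <- confusion(fx$labels[sp$test], pred$label)
    bg_hours <- sum(fx$durations_s[sp$test][fx$labels[sp$test] ==
                                              "background"]) / 3600
    per_split[[s]] <- metrics(cm, total_background_hours = bg_hours)
    confusions[[s]] <- cm
    last_pred <- data.frame(segment_id = fx$segment_ids[sp$test],
                            true_label = fx$labels[sp$test],
                            predicted_label = pred$label,
                            p_seizure = pred$p_seizure,
                            stringsAsFactors = FALSE)
  }
  agg <- if (sc$n_splits >= 2) aggregate_runs(per_split) else per_split[[1]]

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config),
                     file.path(config$out_dir, "config_resolved.yaml"))
    utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    write_evaluation(last_pred, agg, config$out_dir)
    jsonlite::write_json(
      lapply(per_split, unclass),
      file.path(config$out_dir, "metrics_per_split.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fx$exclusions, file.path(config$out_dir, "run_log.csv"),
                     row.names = FALSE)
  }

  list(metrics = agg, per_split = per_split, confusions = confusions,
       features = fx, exclusions = fx$exclusions, config = config)
}
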