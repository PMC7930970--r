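#' Run the full analysis pipeline from a configuration
#'
#' Single entry point wiring the stages together: `simulate` (or load
#' signals from disk), `detect` (R-wave detection per ECG channel),
#' `evaluate` (beat matching and detection metrics of the capacitive
#' channel against the reference), `cough` (TSA analysis per EMG
#' channel), `hrv` (band PSD of both detected trains plus error rates)
#' and `circuit` (front-end report). Every intermediate artifact is
#' written under `out_dir` along with a machine-readable `summary.json`.
#' All randomness flows from the configured seeds, so equal configs give
#' byte-identical summaries.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized top-level fields: `out_dir` (required), `stages`
#'   (character vector, default all), `seed` (integer), `paths` (list
#'   with `signals`/`annotations` when not simulating), `simulate`,
#'   `detect`, `evaluate`, `cough`, `hrv`, `circuit` (per-stage options).
#' @param quiet Suppress progress messages (logged to stderr).
#' @return The summary list, invisibly; also written as
#'   `out_dir/summary.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config requires `out_dir`", call. = FALSE)
  all_stages <- c("simulate", "detect", "evaluate", "cough", "hrv",
                  "circuit")
  stages <- if (is.null(cfg$stages)) all_stages else
    match.arg(cfg$stages, all_stages, several.ok = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)

  # validate all referenced inputs before running any stage
  if (!"simulate" %in% stages) {
    for (p in c(cfg$paths$signals, cfg$paths$annotations)) {
      if (is.null(p) || !file.exists(p)) {
        stop("required input file missing: ",
             if (is.null(p)) "(unset path)" else p, call. = FALSE)
      }
    }
    if (any(c("detect", "evaluate", "cough", "hrv") %in% stages) &&
        is.null(cfg$paths$signals)) {
      stop("config requires `paths$signals` when not simulating",
           call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message("[capsig] ", ...)
  summary <- list(seed = seed, stages = stages)

  channels <- NULL
  annotations <- NULL
  rest_pre <- cfg$simulate$rest_pre %||% 120
  if ("simulate" %in% stages) {
    log_msg("simulate: generating synthetic session (seed ", seed, ")")
    ecg_cfg <- do.call(ecg_sim_config, cfg$simulate$ecg %||% list())
    cough_cfg <- do.call(cough_sim_config, cfg$simulate$cough %||% list())
    session <- synth_cough_session(
      ecg_cfg, cough_cfg,
      fs = cfg$simulate$fs %||% 10000,
      rest_pre = rest_pre,
      rest_post = cfg$simulate$rest_post %||% 30,
      seed = seed)
    paths <- write_session(session, file.path(cfg$out_dir, "session"))
    channels <- session$channels
    annotations <- session$annotations
    # summary records paths relative to out_dir so equal configs give
    # byte-identical summaries regardless of where they are written
    summary$simulate <- list(
      duration_s = session$duration,
      n_truth_rpeaks = length(session$truth_rpeaks),
      n_cycles = nrow(session$truth_cough_windows),
      files = lapply(as.list(paths), function(p) {
        sub(paste0("^", cfg$out_dir, "/?"), "", p)
      }))
  } else {
    channels <- read_signal_table(cfg$paths$signals)
    if (!is.null(cfg$paths$annotations)) {
      annotations <- read_annotations(cfg$paths$annotations)
    }
  }

  trains <- list()
  if ("detect" %in% stages) {
    det_channels <- cfg$detect$channels %||% c("ECG_ref", "cECG")
    for (ch in det_channels) {
      if (!ch %in% names(channels)) {
        stop("detect: channel not found: ", ch, call. = FALSE)
      }
      ts <- channels[[ch]]
      win <- cfg$detect$window %||% c(0, min(rest_pre, ts_duration(ts)))
      train <- detect_ecg(
        slice_series(ts, win[1], win[2]),
        mode = cfg$detect$mode %||% "largest",
        n_waves = cfg$detect$n_waves %||% 5L,
        fraction = cfg$detect$fraction %||% 0.8,
        refractory = cfg$detect$refractory %||% 0.25,
        seed = seed)
      trains[[ch]] <- train
      out <- file.path(cfg$out_dir, paste0("rtimes_", ch, ".csv"))
      data.table::fwrite(data.frame(time_s = train$times), out)
      log_msg("detect: ", ch, " -> ", length(train$times), " beats")
    }
    summary$detect <- lapply(trains, function(tr)
      list(n_beats = length(tr$times), polarity = tr$polarity,
           threshold_V = attr(tr, "threshold")))
  }

  if ("evaluate" %in% stages) {
    ev <- cfg$evaluate %||% list()
    pair <- ev$pair %||% c("cECG", "ECG_ref")
    if (!all(pair %in% names(trains))) {
      stop("evaluate: needs detected trains for ",
           paste(pair, collapse = " and "), call. = FALSE)
    }
    counts <- match_beats(trains[[pair[1]]], trains[[pair[2]]],
                          tol = ev$tol %||% 0.010,
                          pairing_window = ev$pairing_window %||% 0.15)
    metrics <- detection_metrics(counts)
    summary$evaluate <- list(
      counts = counts[c("n_tp", "n_fp", "n_fn", "n_tn")],
      p_sns = metrics$rounded[["p_sns"]],
      p_acc = metrics$rounded[["p_acc"]],
      p_ppv = metrics$rounded[["p_ppv"]])
    jsonlite::write_json(summary$evaluate,
                         file.path(cfg$out_dir, "detection_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("evaluate: P_ACC ", metrics$rounded[["p_acc"]], "%")
  }

  if ("cough" %in% stages) {
    if (is.null(annotations)) {
      stop("cough: annotations are required", call. = FALSE)
    }
    emg_channels <- cfg$cough$channels %||% c("EMG_ref", "cEMG")
    stamps <- annotations$time_s
    summary$cough <- list()
    for (ch in emg_channels) {
      if (!ch %in% names(channels)) {
        stop("cough: channel not found: ", ch, call. = FALSE)
      }
      res <- analyze_cough_emg(channels[[ch]], stamps,
                               rest_window = c(0, rest_pre))
      tab <- rbind(
        data.frame(condition = "coughing", start = res$coughing$start,
                   end = res$coughing$end, tsa = res$tsa_cough),
        data.frame(condition = "resting", start = res$resting$start,
                   end = res$resting$end, tsa = res$tsa_rest))
      data.table::fwrite(tab, file.path(cfg$out_dir,
                                        paste0("tsa_", ch, ".csv")))
      summary$cough[[ch]] <- list(
        md_s = res$md, segment_duration_s = res$segment_duration,
        mean_tsa_cough = mean(res$tsa_cough),
        mean_tsa_rest = mean(res$tsa_rest),
        test = res$comparison$test_name,
        p_value = res$comparison$p_value,
        direction = res$comparison$direction)
      log_msg("cough: ", ch, " ", res$comparison$test_name,
              " p = ", signif(res$comparison$p_value, 3))
    }
    jsonlite::write_json(summary$cough,
                         file.path(cfg$out_dir, "tsa_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("hrv" %in% stages) {
    if (length(trains) < 1L) stop("hrv: needs detected trains",
                                  call. = FALSE)
    hrv_cfg <- cfg$hrv %||% list()
    psds <- lapply(trains, function(tr) {
      band_psd(tachogram(tr, resample_hz = hrv_cfg$resample_hz %||% 8))
    })
    summary$hrv <- list(band_psd = psds)
    if (length(psds) >= 2L) {
      pair <- hrv_cfg$pair %||% c("ECG_ref", "cECG")
      summary$hrv$error_rate <- as.list(
        psd_error_rate(psds[[pair[1]]], psds[[pair[2]]]))
    }
    jsonlite::write_json(summary$hrv,
                         file.path(cfg$out_dir, "hrv.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("hrv: band PSD computed for ",
            paste(names(psds), collapse = ", "))
  }

  if ("circuit" %in% stages) {
    rep <- frontend_report(
      do.call(coupling_spec, cfg$circuit$coupling %||% list()),
      do.call(fvf_spec, cfg$circuit$fvf %||% list()),
      freqs = cfg$circuit$freqs %||% c(10, 15, 20))
    summary$circuit <- unclass(rep)
    jsonlite::write_json(summary$circuit,
                         file.path(cfg$out_dir, "circuit.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("circuit: Z_syn = ",
            signif(rep$z_synthesized_Ohm / 1e12, 3), " TOhm")
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
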