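## ---- end-to-end pipeline orchestration -------------------------------------

#' Pipeline configuration
#'
#' Nested configuration for one reproducible end-to-end run: synthesis ->
#' windowing/MTF -> training -> closed-loop simulation -> scoring. Each
#' stage consumes only its own section. The configuration round-trips
#' through YAML ([read_pipeline_config()], [write_pipeline_config()]).
#'
#' @param recording Arguments for [recording_config()].
#' @param windowing Arguments for [windowing_params()].
#' @param mtf Arguments for [mtf_params()].
#' @param training Arguments for [training_config()].
#' @param timing Arguments for [loop_timing()].
#' @param policy Arguments for [trigger_policy()].
#' @param subject Arguments for [subject_model()].
#' @param n_recordings Total synthetic recordings (train + held-out
#'   sessions).
#' @param n_sessions Held-out recordings used as simulated test sessions.
#' @param threshold Decision threshold (default 0.99).
#' @param test_type `"car"`, `"iart"`, or `"both"`.
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(recording = list(), windowing = list(),
                            mtf = list(), training = list(), timing = list(),
                            policy = list(), subject = list(),
                            n_recordings = 20L, n_sessions = 4L,
                            threshold = 0.99, test_type = "both",
                            out_dir = tempfile("spikeloop-run-"), seed = 7L) {
  structure(list(recording = recording, windowing = windowing, mtf = mtf,
                 training = training, timing = timing, policy = policy,
                 subject = subject, n_recordings = as.integer(n_recordings),
                 n_sessions = as.integer(n_sessions), threshold = threshold,
                 test_type = match.arg(test_type, c("car", "iart", "both")),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

build_stage_objects <- function(config) {
  list(
    recording = do.call(recording_config,
                        c(config$recording, list(seed = config$seed))),
    windowing = do.call(windowing_params, config$windowing),
    mtf = do.call(mtf_params, config$mtf),
    training = do.call(training_config,
                       c(config$training,
                         list(seed = derive_seed(config$seed, "train")))),
    timing = do.call(loop_timing, config$timing),
    policy = do.call(trigger_policy, config$policy),
    subject = do.call(subject_model,
                      c(config$subject,
                        list(seed = derive_seed(config$seed, "subject")))))
}

#' Run the full pipeline
#'
#' Executes synthesis, framing/MTF encoding, detector training, closed-loop
#' session simulation, and scoring, writing session and cohort CSVs plus a
#' run manifest to `config$out_dir`. Deterministic: rerunning the same
#' configuration and seed reproduces identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest`, `sessions` (per test type), `cohort`
#'   summaries, and the trained `model`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sl_stop(sprintf("[%s] %s", name, conditionMessage(e)),
              "spikeloop_stage_failure")
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- build_stage_objects(config)
  cohort <- stage("synth",
                  generate_cohort(obj$recording, config$n_recordings,
                                  seed = config$seed))
  n_tr <- config$n_recordings - config$n_sessions
  if (n_tr < 1) {
    sl_stop("[split] need at least one training recording",
            "spikeloop_stage_failure")
  }
  train_recs <- cohort[seq_len(n_tr)]
  sess_recs <- cohort[n_tr + seq_len(config$n_sessions)]
  have_pos <- any(vapply(train_recs, function(r) sum(r$labels) > 0, TRUE))
  model <- NULL
  rule <- decision_rule(config$threshold)
  if (have_pos) {
    model <- stage("train",
                   train_detector(train_recs, sess_recs, obj$training,
                                  obj$windowing, obj$mtf))
  }
  types <- if (config$test_type == "both") c("car", "iart") else config$test_type
  sessions <- list()
  for (tt in types) {
    rows <- list()
    for (si in seq_along(sess_recs)) {
      rec <- sess_recs[[si]]
      trig <- stage("loop", run_stream(
        rec, model %||% "oracle", obj$timing, obj$policy, rule,
        obj$windowing))
      log <- stage("loop", if (tt == "car") {
        simulate_car_test(trig, obj$subject, obj$timing,
                          seed = derive_seed(config$seed, "car", si))
      } else {
        simulate_iart(trig, obj$subject, obj$timing,
                      seed = derive_seed(config$seed, "iart", si))
      })
      det <- stage("score", {
        cr <- if (is.null(model)) {
          ws <- frame_windows(rec, obj$windowing)
          list(predicted = ws$label, truth = ws$label)
        } else {
          classify_recording(model, rec, rule)
        }
        detection_metrics(cr$predicted, cr$truth)
      })
      rows[[si]] <- session_summary(log, rec, det, patient_id = si)
    }
    sessions[[tt]] <- do.call(rbind, rows)
    utils::write.csv(sessions[[tt]],
                     file.path(config$out_dir,
                               sprintf("sessions_%s.csv", tt)),
                     row.names = FALSE, na = "")
  }
  cohorts <- lapply(sessions, cohort_summary)
  for (tt in names(cohorts)) {
    utils::write.csv(cohorts[[tt]],
                     file.path(config$out_dir, sprintf("cohort_%s.csv", tt)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    version = as.character(utils::packageVersion("spikeloop")),
    n_recordings = config$n_recordings, n_sessions = config$n_sessions,
    stages = c("synth", "train", "loop", "score", "summarize"),
    outputs = list.files(config$out_dir),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, sessions = sessions, cohort = cohorts,
                 model = model))
}

#' Render a plain-text session report
#'
#' Prints the session row, detection metrics, the cumulative crash-risk
#' readout, and flags a reaction-time prolongation above 100 ms as
#' clinically relevant (the published threshold for meaningful slowing); a
#' missing RT prolongation is reported as not assessable.
#'
#' @param session One-row session summary data frame.
#' @param cohort Optional `cohort_summary` for context.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
make_report <- function(session, cohort = NULL) {
  lines <- c(sprintf("Session report - patient %s", session$patient),
             sprintf("  duration: %.1f min, triggers: %d (%d during bursts)",
                     session$duration_min, session$n_triggers,
                     session$n_ieds))
  if (!is.null(session$delta_rt_ms)) {
    drt <- session$delta_rt_ms
    flag <- if (is.na(drt)) {
      "not assessable (no RT prolongation measured)"
    } else if (drt > 100) {
      sprintf("clinically relevant (>100 ms): %.1f ms", drt)
    } else {
      sprintf("below the 100 ms relevance threshold: %.1f ms", drt)
    }
    lines <- c(lines, paste0("  RT prolongation: ", flag))
    if (!is.na(drt)) {
      lines <- c(lines, sprintf("  cumulative crash risk: %.1f%%",
                                cumulative_crash_risk(drt)))
    }
  }
  for (fld in c("sensitivity", "specificity", "fp_rate_per_min")) {
    if (!is.null(session[[fld]]) && !is.na(session[[fld]])) {
      lines <- c(lines, sprintf("  %s: %.2f", fld, session[[fld]]))
    }
  }
  if (!is.null(cohort)) {
    lines <- c(lines, sprintf("  (cohort of %d columns summarized)",
                              nrow(cohort)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
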