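# One-call end-to-end pipeline over a synthetic (or loaded) study.

#' Pipeline configuration
#'
#' Bundles every analysis default: simulation settings, detector
#' thresholds, window geometry, permutation and ensemble sizes, and the
#' master seed. Defaults mirror the analysis conventions used
#' throughout the package (thresholds in SD units, 4 s / step 3 s
#' windows, 150 ms discharge grouping with a > 60% channel gate);
#' ensemble sizes default to a desk-scale 200 ensembles x 50 trees
#' (the full-scale 1000 x 100 is a configuration choice).
#'
#' @param synth a [synth_config()] describing the simulated study.
#' @param n_seizures seizures to simulate (>= 4 for model training plus
#'   a withheld seizure).
#' @param channel_id electrode used for single-site features.
#' @param onset_k calcium onset threshold, SD units (default 5).
#' @param hg_k high-gamma event threshold, SD units (default 2.5).
#' @param wave_k discharge peak threshold, SD units (default 2).
#' @param max_gap,min_frac discharge grouping parameters.
#' @param win,step feature window length/step, seconds.
#' @param n_perm rank-reliability permutations.
#' @param n_ensembles,n_trees,cv_folds,min_leaf ensemble settings.
#' @param epoch_frac epoch fraction for first/last comparisons.
#' @param analysis_rate rate for band analyses, Hz.
#' @param importance logical: compute OOB importance summaries.
#' @param seed master seed for every stochastic stage.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            n_seizures = 4,
                            channel_id = 6,
                            onset_k = 5, hg_k = 2.5, wave_k = 2,
                            max_gap = 0.150, min_frac = 0.6,
                            win = 4, step = 3,
                            n_perm = 1000,
                            n_ensembles = 200, n_trees = 50,
                            cv_folds = 5, min_leaf = 5,
                            epoch_frac = 0.25,
                            analysis_rate = 2000,
                            importance = TRUE,
                            seed = 1,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full multimodal analysis pipeline
#'
#' Executes simulate -> calcium onsets -> phase coupling -> traveling
#' waves -> features -> speed model -> epoch comparison on a synthetic
#' study, returning every stage's outputs plus a run report of counts.
#' A stage failure aborts with the stage name; prior results are
#' returned in the error-free prefix when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list with elements `study`, `onsets`, `reliability`, `phase`,
#'   `waves`, `direction_stats`, `speed_epochs`, `features`, `model`,
#'   `epochs`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  study <- stage("simulate",
                 generate_study(cfg$synth, cfg$n_seizures, seed = cfg$seed))

  onsets <- stage("onsets", lapply(study, function(sz) {
    tr <- smooth_traces(sz$calcium)
    detect_onsets(tr, k = cfg$onset_k)
  }))
  rank_matrix <- vapply(onsets, `[[`, numeric(cfg$synth$n_cells), "ranks")
  reliability <- stage("onsets", rank_reliability(
    rank_matrix, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 21L)))
  vectors <- stage("onsets", lapply(seq_along(study), function(i)
    onset_direction(onsets[[i]], study[[i]]$calcium$centroids)))

  phase <- stage("phase", lapply(study, function(sz) {
    ds <- downsample_signal(
      sz$recording$signals[cfg$channel_id, ], sz$recording$rate,
      target_rate = min(cfg$analysis_rate, sz$recording$rate))
    lf <- analytic_signal(bandpass(ds$x, ds$rate, c(4, 30)), ds$rate)
    hg <- analytic_signal(bandpass(ds$x, ds$rate, c(80, 150)), ds$rate)
    ev <- detect_hg_events(hg, k = cfg$hg_k)
    ps <- phases_at_events(lf, ev)
    null <- with_seed(derive_seed(cfg$seed, 22L),
                      null_phases(length(ps$phases)))
    list(events = ev, phases = ps,
         test = circular_tests(ps$phases, null))
  }))

  waves <- stage("wave", lapply(study, function(sz)
    wave_events(sz$recording, k = cfg$wave_k,
                max_gap = cfg$max_gap, min_frac = cfg$min_frac)))
  dirstats <- stage("wave", direction_stats(
    lapply(waves, function(w) w$direction_rad[!w$degenerate])))
  epochs_speed <- stage("wave", lapply(waves, function(w)
    speed_epoch_comparison(w$t_center_s[!w$degenerate],
                           w$speed_mm_s[!w$degenerate],
                           frac = cfg$epoch_frac)))

  features <- stage("features", lapply(seq_along(study), function(i)
    build_feature_table(study[[i]]$recording, study[[i]]$calcium,
                        cfg$channel_id, waves[[i]],
                        win = cfg$win, step = cfg$step,
                        analysis_rate = cfg$analysis_rate)))

  model <- stage("model", {
    train_tabs <- features[1:3]
    training <- assemble_training(train_tabs,
                                  seed = derive_seed(cfg$seed, 23L))
    models <- train_ensembles(training, cfg$n_ensembles, cfg$n_trees,
                              cfg$cv_folds,
                              seed = derive_seed(cfg$seed, 24L),
                              min_leaf = cfg$min_leaf)
    report <- evaluate_ensembles(models, features[[cfg$n_seizures]],
                                 importance = cfg$importance)
    list(training = training, models = models, evaluation = report)
  })

  epochs <- stage("epochs", feature_epoch_comparison(
    features[1:3], features = feature_names(), frac = cfg$epoch_frac))

  report <- list(
    seed = cfg$seed,
    n_seizures = cfg$n_seizures,
    n_cells = cfg$synth$n_cells,
    recruitment_duration_s = vapply(onsets, `[[`, 0,
                                    "recruitment_duration_s"),
    n_hg_events = vapply(phase, function(p) length(p$events), 0),
    n_discharge_events = vapply(waves, nrow, 0L),
    n_feature_rows = vapply(features, nrow, 0L),
    files = character(0))

  out <- list(study = study, onsets = onsets, reliability = reliability,
              onset_vectors = vectors, phase = phase, waves = waves,
              direction_stats = dirstats, speed_epochs = epochs_speed,
              features = features, model = model, epochs = epochs,
              report = report)
  if (!is.null(cfg$out_dir)) out$report$files <- write_outputs(cfg, out)
  out
}

write_outputs <- function(cfg, out) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wf <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    if (is.data.frame(obj)) data.table::fwrite(obj, p)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
    files <<- c(files, p)
  }
  for (i in seq_along(out$waves))
    wf(out$waves[[i]], sprintf("discharges_seizure%d.csv", i))
  for (i in seq_along(out$features))
    wf(out$features[[i]], sprintf("features_seizure%d.csv", i))
  wf(out$epochs, "feature_epochs.csv")
  wf(list(kendall_w = out$reliability$kendall_w,
          kendall_p = out$reliability$kendall_p,
          spearman_r = out$reliability$spearman_r,
          recruitment_duration_s = out$report$recruitment_duration_s),
     "reliability.json")
  if (!is.null(out$model$evaluation$importance_summary))
    wf(out$model$evaluation$importance_summary, "importance.csv")
  wf(out$report[setdiff(names(out$report), "files")], "run_report.json")
  files
}
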