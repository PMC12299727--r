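# End-to-end experiment: simulate -> preprocess -> marker events (M1) ->
# train/detect (M2) -> cycles -> quality filter -> aggregate -> agreement
# report, reproducible from a single master seed.

#' Experiment configuration
#'
#' Bundles all stage parameters. Every stage seed is derived deterministically
#' from the master `seed` (simulation uses the seed itself; the subject split,
#' the four detectors and the bootstrap use fixed offsets from it), so a single
#' integer reproduces the whole experiment.
#'
#' @param seed Master seed.
#' @param simulation A [sim_config()]; its own seed is overridden by `seed`.
#' @param filter Low-pass [butter_spec()] applied to IMU and marker data.
#' @param window List `length`, `hop`, `band` for [segment_windows()] /
#'   [label_windows()]. The default band `c(0.25, 0.75)` marks the window
#'   whose centre lies within half a hop of the event, so every event becomes
#'   a (unique) positive training example; narrower bands than the hop leave
#'   a fraction of events with no positive window at all, which makes those
#'   events untrainable and hence undetectable.
#' @param model A [detector_spec()]; per-stream seeds are derived from `seed`.
#' @param split_fraction Training fraction for the subject-wise split.
#' @param threshold,refractory Event reconstruction parameters.
#' @param stride_bounds Plausible stride range for [filter_cycles()].
#' @param match_tolerance Cycle matching tolerance in seconds.
#' @param n_boot Bootstrap resamples for rRMSE confidence intervals.
#' @param analysis_rate Common analysis rate in Hz (the mocap rate).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 20201L,
                              simulation = sim_config(),
                              filter = butter_spec(),
                              window = list(length = 0.2, hop = 0.1,
                                            band = c(0.25, 0.75)),
                              model = detector_spec(),
                              split_fraction = 0.8,
                              threshold = 0.5, refractory = 0.4,
                              stride_bounds = c(0.4, 2.5),
                              match_tolerance = 0.25,
                              n_boot = 1000,
                              analysis_rate = 100) {
  seed <- as.integer(seed)
  simulation$seed <- seed
  cfg <- structure(
    list(seed = seed, simulation = simulation, filter = filter,
         window = window, model = model, split_fraction = split_fraction,
         threshold = threshold, refractory = refractory,
         stride_bounds = stride_bounds, match_tolerance = match_tolerance,
         n_boot = n_boot, analysis_rate = analysis_rate),
    class = "experiment_config")
  validate_config(cfg)
}

# offset-derived stage seeds, kept inside the 32-bit integer range
stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) + offset) %% (.Machine$integer.max - 1))
}

#' Validate and normalise an experiment configuration
#'
#' Checks cross-stage invariants (filter cutoff below the analysis Nyquist,
#' increasing label band inside \[0, 1\], usable split fraction, positive
#' windowing), fills missing window defaults, and reports all problems at once.
#'
#' @param config An [experiment_config()]-like list.
#' @return The normalised config; aborts with an aggregated message on error.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  w <- config$window
  w$length <- w$length %||% 0.2
  w$hop <- w$hop %||% 0.1
  w$band <- w$band %||% c(0.25, 0.75)
  if (w$length <= 0 || w$hop <= 0) errs <- c(errs, "window length/hop must be positive")
  if (length(w$band) != 2 || w$band[1] > w$band[2] ||
      any(w$band < 0) || any(w$band > 1)) {
    errs <- c(errs, "label band must be an increasing pair inside [0, 1]")
  }
  config$window <- w
  if (config$filter$cutoff >= config$analysis_rate / 2) {
    errs <- c(errs, sprintf("filter cutoff %.1f Hz is not below the Nyquist of the %.0f Hz analysis rate",
                            config$filter$cutoff, config$analysis_rate))
  }
  if (config$split_fraction <= 0 || config$split_fraction >= 1) {
    errs <- c(errs, "split fraction must be in (0, 1)")
  }
  ns <- config$simulation$n_subjects
  if (round(config$split_fraction * ns) >= ns ||
      round(config$split_fraction * ns) < 1) {
    errs <- c(errs, "split fraction leaves an empty train or test set")
  }
  if (length(config$stride_bounds) != 2 ||
      diff(config$stride_bounds) <= 0 || any(config$stride_bounds <= 0)) {
    errs <- c(errs, "stride bounds must be an increasing positive pair")
  }
  if (length(errs)) {
    abort(paste0("Invalid experiment configuration:\n",
                 paste0("- ", errs, collapse = "\n")))
  }
  config
}

with_stage <- function(stage, trial_id = NULL, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s'%s failed: %s", stage,
                  if (is.null(trial_id)) "" else paste0(" (trial ", trial_id, ")"),
                  conditionMessage(e)))
  })
}

#' Run the full experiment
#'
#' Executes the pipeline end to end on a synthetic cohort: per-trial
#' simulation, marker-based reference events (M1), IMU preprocessing and
#' window labeling, subject-wise 80/20 split, per-stream detector training,
#' event detection on the test subjects (M2), cycle computation and quality
#' filtering for both pipelines, per-condition matched-cycle rRMSE, and the
#' agreement report.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, all intermediates (manifest,
#'   events, cycles, condition means, report tables, run info) are persisted as
#'   CSV.
#' @param quiet Suppress progress messages.
#' @return A list of class `gait_experiment` with elements `report`
#'   (an `agreement_report`), `cycle_rrmse`, `means_m1`, `means_m2`, `split`,
#'   `detector_summary`, `manifest`, `exclusions`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) inform(sprintf(...))
  simc <- config$simulation
  plan <- with_stage("plan", NULL, cohort_plan(simc))
  manifest <- plan$manifest
  streams <- c("HS_L", "HS_R", "TO_L", "TO_R")

  say("Simulating and preprocessing %d trials ...", nrow(manifest))
  trials <- vector("list", nrow(manifest))
  names(trials) <- manifest$trial_id
  for (id in manifest$trial_id) {
    trial <- with_stage("simulate", id, simulate_planned_trial(plan, id, simc))
    ev_m1 <- with_stage("marker_events", id, marker_events(trial, config$filter))
    ws <- with_stage("signal_prep", id, prep_windows(
      trial, ev_m1, rate = config$analysis_rate, spec = config$filter,
      length = config$window$length, hop = config$window$hop,
      band = config$window$band))
    cyc_m1 <- with_stage("gait_params", id,
                         compute_cycles(ev_m1) %>%
                           filter_cycles(trial$transitions,
                                         config$stride_bounds))
    trials[[id]] <- list(ws = ws, events_m1 = ev_m1, cycles_m1 = cyc_m1,
                         transitions = trial$transitions)
  }

  split <- with_stage("split", NULL, split_by_subject(
    manifest, config$split_fraction, stage_seed(config$seed, 1000)))
  train_ids <- manifest$trial_id[manifest$subject %in% split$train_subjects]
  test_ids <- manifest$trial_id[manifest$subject %in% split$test_subjects]

  detectors <- list()
  for (i in seq_along(streams)) {
    s <- streams[i]
    say("Training detector %s on %d trials ...", s, length(train_ids))
    spec_s <- config$model
    spec_s$seed <- stage_seed(config$seed, 2000 + i)
    detectors[[s]] <- with_stage("train", s, train_detector(
      lapply(trials[train_ids], `[[`, "ws"), s, spec_s))
  }

  say("Detecting events on %d test trials ...", length(test_ids))
  cycles_m1 <- list(); cycles_m2 <- list(); rr_rows <- list()
  events_m2_all <- list()
  for (id in test_ids) {
    tr <- trials[[id]]
    ev_m2 <- with_stage("detect", id, detect_events(
      detectors, tr$ws, config$threshold, config$refractory))
    events_m2_all[[id]] <- mutate(ev_m2, trial_id = id)
    cyc_m2 <- with_stage("gait_params", id,
                         compute_cycles(ev_m2) %>%
                           filter_cycles(tr$transitions, config$stride_bounds))
    cycles_m1[[id]] <- mutate(tr$cycles_m1, trial_id = id)
    cycles_m2[[id]] <- mutate(cyc_m2, trial_id = id)

    matched <- with_stage("match", id, match_cycles(
      tr$cycles_m1, cyc_m2, config$match_tolerance))
    meta <- manifest[manifest$trial_id == id, ]
    for (p in c("stride", "stance", "swing", "double_support")) {
      v1 <- matched[[paste0(p, "_m1")]]
      v2 <- matched[[paste0(p, "_m2")]]
      keep <- !is.na(v1) & !is.na(v2)
      if (sum(keep) >= 3) {
        rr_rows[[length(rr_rows) + 1]] <- tibble(
          subject = meta$subject, speed = meta$speed,
          placement = meta$placement, parameter = p,
          rrmse = rrmse(v1[keep], v2[keep]), n_pairs = sum(keep))
      }
    }
  }
  cycle_rrmse <- bind_rows(rr_rows)
  cycles_m1 <- bind_rows(cycles_m1)
  cycles_m2 <- bind_rows(cycles_m2)

  say("Building agreement report ...")
  # evaluation covers the test subjects only, so aggregate against their
  # share of the manifest (otherwise every train condition looks "omitted")
  manifest_test <- manifest[manifest$trial_id %in% test_ids, ]
  means_m1 <- with_stage("aggregate", NULL,
                         aggregate_by_condition(cycles_m1, manifest_test))
  means_m2 <- with_stage("aggregate", NULL,
                         aggregate_by_condition(cycles_m2, manifest_test))
  report <- with_stage("report", NULL, build_report(
    cycle_rrmse, means_m1, means_m2, config$n_boot,
    stage_seed(config$seed, 3000)))

  exclusions <- purrr::map_dfr(trials, ~ attr(.x$cycles_m1,
                                              "exclusion_tally")) %>%
    group_by(.data$reason) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(pipeline = "marker")

  out <- structure(
    list(report = report, cycle_rrmse = cycle_rrmse,
         means_m1 = means_m1, means_m2 = means_m2, split = split,
         detector_summary = purrr::map_dfr(detectors, glance),
         detectors = detectors,
         events_m2 = bind_rows(events_m2_all),
         cycles_m1 = cycles_m1, cycles_m2 = cycles_m2,
         manifest = manifest, exclusions = exclusions, config = config),
    class = "gait_experiment")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(cycles_m1, file.path(out_dir, "cycles_m1.csv"))
    readr::write_csv(cycles_m2, file.path(out_dir, "cycles_m2.csv"))
    readr::write_csv(cycle_rrmse, file.path(out_dir, "cycle_rrmse.csv"))
    readr::write_csv(out$events_m2, file.path(out_dir, "events_model.csv"))
    readr::write_csv(out$detector_summary,
                     file.path(out_dir, "detector_summary.csv"))
    readr::write_csv(tibble(role = c(rep("train", length(split$train_subjects)),
                                     rep("test", length(split$test_subjects))),
                            subject = c(split$train_subjects,
                                        split$test_subjects)),
                     file.path(out_dir, "split_plan.csv"))
    write_report(report, out_dir)
    readr::write_csv(tibble(key = c("seed", "n_subjects", "package_version"),
                            value = c(config$seed, simc$n_subjects,
                                      as.character(utils::packageVersion("gaitwin")))),
                     file.path(out_dir, "run_info.csv"))
  }
  out
}

#' @export
print.gait_experiment <- function(x, ...) {
  g <- glance(x$report)
  cat(sprintf(paste0("<gait_experiment> %d trials | test subjects: %s\n",
                     "  stride rRMSE median %.2f%% | %%within LoA %.1f | stride r %.3f\n"),
              nrow(x$manifest), paste(x$split$test_subjects, collapse = ", "),
              g$stride_rrmse_median, g$pct_within_loa, g$stride_pearson_r))
  invisible(x)
}
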