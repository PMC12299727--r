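# Cohort-level generation: one trial per subject x speed x placement, fully
# reproducible from the master seed via per-trial derived seeds.

#' Plan a synthetic cohort
#'
#' Draws the subject profiles and derives one RNG seed per trial from the
#' master seed, so trials can be (re)generated independently and in any order.
#'
#' @param config A [sim_config()] with `n_subjects >= 2`.
#' @return A list with `profiles` (tibble) and `manifest` (tibble with one row
#'   per subject x speed x placement and a derived per-trial seed).
#' @export
cohort_plan <- function(config = sim_config()) {
  if (config$n_subjects < 2) {
    abort("A cohort needs at least 2 subjects (the subject-wise train/test split is impossible otherwise).")
  }
  set.seed(config$seed)
  profiles <- draw_subject_profiles(config$n_subjects, config)
  manifest <- tidyr::expand_grid(
    subject = profiles$subject_id,
    speed = config$speeds,
    placement = config$placements
  ) %>%
    mutate(
      trial_id = sprintf("%s_v%0.2f_%s", .data$subject, .data$speed,
                         .data$placement),
      trial_seed = sample.int(.Machine$integer.max - 1L, dplyr::n())
    ) %>%
    select("trial_id", "subject", "speed", "placement", "trial_seed")
  list(profiles = profiles, manifest = manifest)
}

# simulate a single planned trial by manifest row
simulate_planned_trial <- function(plan, trial_id, config) {
  row <- plan$manifest[plan$manifest$trial_id == trial_id, ]
  if (nrow(row) != 1) abort(sprintf("Unknown trial id '%s'.", trial_id))
  profile <- plan$profiles[plan$profiles$subject_id == row$subject, ]
  set.seed(row$trial_seed)
  simulate_trial(profile, row$speed, row$placement, config)
}

#' Generate a full synthetic cohort
#'
#' Simulates one trial for every subject x speed x placement cell. With
#' `out_dir` the trials are written as plain CSV files (one directory per
#' trial: `imu.csv`, `markers.csv`, `events.csv`, `transitions.csv`) plus a
#' cohort `manifest.csv`; otherwise all trials are returned in memory, which is
#' only advisable for small configurations.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param force Overwrite an existing `out_dir`.
#' @return A list with `profiles`, `manifest` and (when `out_dir` is `NULL`) a
#'   named list `trials`.
#' @export
generate_cohort <- function(config = sim_config(), out_dir = NULL,
                            force = FALSE) {
  plan <- cohort_plan(config)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
      abort(sprintf("Cohort directory '%s' exists; use `force = TRUE` to overwrite.", out_dir))
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in plan$manifest$trial_id) {
      trial <- simulate_planned_trial(plan, id, config)
      write_trial(trial, file.path(out_dir, id))
    }
    readr::write_csv(plan$manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(plan$profiles, file.path(out_dir, "profiles.csv"))
    return(invisible(list(profiles = plan$profiles, manifest = plan$manifest,
                          out_dir = out_dir)))
  }
  trials <- lapply(plan$manifest$trial_id, simulate_planned_trial,
                   plan = plan, config = config)
  names(trials) <- plan$manifest$trial_id
  list(profiles = plan$profiles, manifest = plan$manifest, trials = trials)
}

#' Write one trial to a directory of CSV files
#'
#' Streams are written with times in seconds to six decimal places:
#' `imu.csv` (t, acc_x..gyr_z), `markers.csv` (t, calc_L_z, calc_R_z,
#' meta_L_z, meta_R_z), `events.csv` (t, event, side) and `transitions.csv`.
#'
#' @param trial A `gait_trial`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) mutate(df, across(dplyr::where(is.numeric),
                                        ~ round(.x, 6)))
  readr::write_csv(fmt(trial$imu), file.path(dir, "imu.csv"))
  readr::write_csv(fmt(trial$markers), file.path(dir, "markers.csv"))
  readr::write_csv(
    fmt(trial$events %>% select(t = "time", event = "type", "side")),
    file.path(dir, "events.csv"))
  readr::write_csv(tibble(t = round(as.numeric(trial$transitions), 6)),
                   file.path(dir, "transitions.csv"))
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir Trial directory.
#' @return A `gait_trial` (without analytic truth cycles).
#' @export
read_trial <- function(dir) {
  imu <- readr::read_csv(file.path(dir, "imu.csv"), show_col_types = FALSE)
  markers <- readr::read_csv(file.path(dir, "markers.csv"),
                             show_col_types = FALSE)
  ev <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  tr <- readr::read_csv(file.path(dir, "transitions.csv"),
                        show_col_types = FALSE)
  structure(
    list(imu = imu, markers = markers,
         events = tibble(time = ev$t, type = ev$event, side = ev$side,
                         source = "truth"),
         transitions = tr$t, truth_cycles = NULL,
         subject = NA_character_, speed = NA_real_, placement = NA_character_,
         duration = nrow(imu) / infer_rate(imu$t),
         fs_imu = infer_rate(imu$t), fs_mocap = infer_rate(markers$t)),
    class = "gait_trial"
  )
}
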