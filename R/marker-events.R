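# Reference ("experimental", M1) gait events from vertical marker
# trajectories: heel strike is the local minimum of the calcaneus marker in
# the first 30% of the interval between successive foot motion peaks; toe-off
# is the local minimum of the metatarsal marker between 40% and 80% of that
# same interval.

# topographic prominence of local maxima: height above the higher of the two
# saddle minima separating the peak from the nearest higher terrain
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    min_l <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)])
             else min(left, h)
    right <- x[seq(p + 1, length(x))]
    higher_r <- which(right > h)
    min_r <- if (length(higher_r)) min(x[(p + 1):(p + min(higher_r) - 1)])
             else min(right, h)
    h - max(min_l, min_r)
  }, numeric(1))
}

#' Find foot motion peaks in a vertical marker trajectory
#'
#' Detects the swing apex of the (low-pass filtered) calcaneus vertical
#' trajectory: local maxima with at least `min_prominence` of topographic
#' prominence and pairwise separation of at least `min_separation` (higher
#' peaks win ties). On the simulator there is exactly one such apex per stride;
#' the intervals between successive apexes define the per-stride search bands
#' for heel strikes and toe-offs.
#'
#' @param df Tibble with columns `t` and one marker channel (first non-`t`
#'   numeric column is used).
#' @param min_prominence Minimum prominence, in the channel's units (default
#'   10 mm).
#' @param min_separation Minimum peak separation in seconds (default 0.4, below
#'   any plausible stride time at walking speeds).
#' @return Tibble `time`, `value`, `prominence`, sorted by time (possibly
#'   empty).
#' @export
find_foot_motion_peaks <- function(df, min_prominence = 10,
                                   min_separation = 0.4) {
  ch <- channel_cols(df)[1]
  x <- df[[ch]]
  n <- length(x)
  if (n < 3) return(tibble(time = numeric(0), value = numeric(0),
                           prominence = numeric(0)))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(tibble(time = numeric(0), value = numeric(0),
                                   prominence = numeric(0)))
  prom <- peak_prominence(x, cand)
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  # enforce separation, keeping the higher peak
  ord <- order(x[cand], decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(df$t[cand[i]] - df$t[cand[sel]]) >= min_separation)) {
      sel <- c(sel, i)
    }
  }
  sel <- sort(cand[sel])
  tibble(time = df$t[sel], value = x[sel],
         prominence = prom[match(sel, cand)])
}

# minimum of a band: local minima of the trajectory are preferred; if the
# band contains none, its global minimum (possibly at a boundary) is used;
# ties break to the earlier time. Whether a band sample is a local minimum
# is judged against its neighbours in the full series, not only the samples
# inside the band: a genuine trajectory minimum that happens to fall on the
# band's edge sample must not lose to an interior ripple.
band_minimum <- function(t, x, lo, hi) {
  idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  if (length(idx) < 3) return(NA_real_)
  n <- length(x)
  interior <- idx[idx > 1L & idx < n]
  loc <- interior[x[interior] < x[interior - 1L] & x[interior] <= x[interior + 1L]]
  j <- if (length(loc)) loc[which.min(x[loc])] else idx[which.min(x[idx])]
  t[j]
}

detect_band_events <- function(df, peaks, frac, type, side) {
  ch <- channel_cols(df)[1]
  times <- numeric(0)
  p <- peaks$time
  if (length(p) >= 2) {
    for (i in seq_len(length(p) - 1)) {
      delta <- p[i + 1] - p[i]
      tt <- band_minimum(df$t, df[[ch]], p[i] + frac[1] * delta,
                         p[i] + frac[2] * delta)
      if (is.na(tt)) {
        warn(sprintf("Band %d shorter than 3 samples; skipped.", i))
        next
      }
      times <- c(times, tt)
    }
  }
  tibble(time = times, type = type, side = side, source = "marker")
}

#' Detect heel strikes from the calcaneus trajectory
#'
#' For each pair of successive foot motion peaks `(p_i, p_{i+1})`, returns the
#' minimum of the calcaneus vertical position restricted to the first 30% of
#' the interval, `[p_i, p_i + 0.30 (p_{i+1} - p_i)]`. Local minima of the
#' trajectory (judged against full-series neighbours, so a minimum on the
#' band's edge sample still counts) are preferred; on monotone bands the
#' boundary minimum is used, and ties break to the earlier time.
#'
#' @param df Tibble with `t` and the calcaneus vertical channel (filtered).
#' @param peaks Result of [find_foot_motion_peaks()] (>= 2 peaks for any
#'   output).
#' @param side `"L"` or `"R"`.
#' @return Event tibble (`time`, `type`, `side`, `source`).
#' @export
detect_heel_strikes <- function(df, peaks, side) {
  detect_band_events(df, peaks, c(0, 0.30), "HS", side)
}

#' Detect toe-offs from the metatarsal trajectory
#'
#' As [detect_heel_strikes()], with the search band between 40% and 80% of the
#' inter-peak interval.
#'
#' @inheritParams detect_heel_strikes
#' @export
detect_toe_offs <- function(df, peaks, side) {
  detect_band_events(df, peaks, c(0.40, 0.80), "TO", side)
}

#' Merge and validate per-side event streams
#'
#' Sorts heel strikes and toe-offs by time, drops events with non-increasing
#' times within their stream, and flags alternation breaks (e.g. two
#' consecutive heel strikes without an intervening toe-off). Flagged events are
#' retained -- downstream cycle computation marks the affected cycles
#' incomplete -- and reported in the `"alternation_breaks"` attribute.
#'
#' @param hs,to Event tibbles for one side.
#' @param side `"L"` or `"R"`.
#' @return Combined event tibble sorted by time.
#' @export
assemble_event_streams <- function(hs, to, side) {
  ev <- bind_rows(hs, to) %>%
    filter(.data$side == !!side) %>%
    arrange(.data$time, .data$type)
  for (ty in c("HS", "TO")) {
    idx <- which(ev$type == ty)
    tt <- ev$time[idx]
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      keep <- c(TRUE, diff(tt) > 0)
      ev <- ev[-idx[!keep], ]
      inform(sprintf("Dropped %d non-increasing %s events (side %s).",
                     sum(!keep), ty, side))
    }
  }
  breaks <- which(ev$type[-1] == ev$type[-nrow(ev)])
  if (length(breaks)) {
    inform(sprintf("%d alternation break(s) in side-%s stream.",
                   length(breaks), side))
  }
  attr(ev, "alternation_breaks") <- length(breaks)
  ev
}

#' Run the full marker-based event pipeline on a trial
#'
#' Low-pass filters the marker trajectories, finds per-side foot motion peaks
#' on the calcaneus channel, and extracts heel strikes and toe-offs by the
#' band-minimum rules.
#'
#' @param trial A `gait_trial`.
#' @param spec Marker low-pass [butter_spec()].
#' @param min_prominence,min_separation Peak detection parameters, see
#'   [find_foot_motion_peaks()].
#' @return Event tibble with `source = "marker"` for both sides.
#' @export
marker_events <- function(trial, spec = butter_spec(),
                          min_prominence = 10, min_separation = 0.4) {
  mk <- lowpass_butterworth(trial$markers, spec)
  out <- list()
  for (side in c("L", "R")) {
    calc <- mk %>% select("t", all_of(paste0("calc_", side, "_z")))
    meta <- mk %>% select("t", all_of(paste0("meta_", side, "_z")))
    peaks <- find_foot_motion_peaks(calc, min_prominence, min_separation)
    hs <- detect_heel_strikes(calc, peaks, side)
    to <- detect_toe_offs(meta, peaks, side)
    out[[side]] <- assemble_event_streams(hs, to, side)
  }
  bind_rows(out) %>% arrange(.data$time)
}
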