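# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are written as directly as possible (explicit formulas) and share no
# code path with the package implementations. The statistical kernels are
# compared bit for bit, which is only well-defined under a pinned arithmetic
# convention: single-pass sum()-based reductions, evaluated in the order the
# formulas are written. (An R-level loop accumulates in double precision while
# sum() accumulates in long double, so even "the same" formula written as a
# loop differs in the last ulp.)

# ---- brute-force statistical kernels ---------------------------------------

brute_rrmse <- function(m1, m2) {
  n <- length(m1)
  100 * sqrt(sum((m2 - m1)^2) / n) / (sum(m1) / n)
}

brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  r <- num / den
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p)
}

brute_bland_altman <- function(m1, m2) {
  d <- m1 - m2
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  list(bias = bias, loa_low = lo, loa_high = hi,
       pct_within = 100 * sum(d >= lo & d <= hi) / n)
}

# ---- brute-force marker-event oracle ---------------------------------------

# Exhaustive per-sample scan for the band minimum between successive peaks:
# every sample whose time lies in [p_i + frac1*delta, p_i + frac2*delta] is
# examined and the global minimum taken (earliest on ties).
oracle_band_scan <- function(t, x, peaks, frac1, frac2) {
  out <- numeric(0)
  for (i in seq_len(length(peaks) - 1)) {
    delta <- peaks[i + 1] - peaks[i]
    lo <- peaks[i] + frac1 * delta
    hi <- peaks[i] + frac2 * delta
    idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
    if (length(idx) < 3) next
    best <- idx[1]
    for (j in idx) if (x[j] < x[best]) best <- j
    out <- c(out, t[best])
  }
  out
}

# ---- brute-force double support --------------------------------------------

# 1 ms-grid occupancy count: fraction of grid points inside [h0, to1] at which
# the opposite foot is in stance.
brute_double_support <- function(h0, to1, opp_hs, opp_to, dt = 0.001) {
  grid <- seq(h0, to1, by = dt)
  in_stance <- vapply(grid, function(g) {
    prev_hs <- opp_hs[opp_hs <= g]
    prev_to <- opp_to[opp_to <= g]
    last_hs <- if (length(prev_hs)) max(prev_hs) else -Inf
    last_to <- if (length(prev_to)) max(prev_to) else -Inf
    last_hs >= last_to  # most recent opposite event is a heel strike
  }, logical(1))
  sum(in_stance) * dt
}

# ---- shared fixtures --------------------------------------------------------

# A small, fast trial; memoised across tests within a file run.
.trial_cache <- new.env(parent = emptyenv())
quick_trial <- function(seed = 1L, duration = 15, marker_noise = 0.5,
                        placement = "trouser", speed = 1.25,
                        fs_imu = 400) {
  key <- paste(seed, duration, marker_noise, placement, speed, fs_imu,
               sep = "|")
  if (!is.null(.trial_cache[[key]])) return(.trial_cache[[key]])
  cfg <- sim_config(fs_imu = fs_imu, marker_noise = marker_noise, seed = seed)
  set.seed(seed)
  prof <- draw_subject_profiles(1, cfg)
  set.seed(seed + 1L)
  trial <- simulate_trial(prof, speed, placement, cfg, duration = duration)
  .trial_cache[[key]] <- trial
  trial
}

# Match each detected event to its nearest truth event of the same stream and
# return the absolute errors (seconds); detected events without a truth event
# within `max_gap` are reported as Inf.
event_errors <- function(detected, truth, max_gap = 0.5) {
  streams <- unique(paste(detected$type, detected$side))
  errs <- numeric(0)
  for (s in streams) {
    parts <- strsplit(s, " ")[[1]]
    dt <- detected$time[detected$type == parts[1] & detected$side == parts[2]]
    tt <- truth$time[truth$type == parts[1] & truth$side == parts[2]]
    for (d in dt) {
      gap <- min(abs(d - tt))
      errs <- c(errs, if (gap <= max_gap) gap else Inf)
    }
  }
  errs
}
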