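# Preprocessing chain: resampling, zero-phase filtering, robust scaling,
# windowing and window labeling.

test_that("zero-phase Butterworth halves the gain at cutoff without lag", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  spec <- butter_spec(order = 4, cutoff = 10, zero_phase = TRUE)
  # sinusoid exactly at the cutoff: two passes of |H| = 1/sqrt(2) give 1/2
  x <- sin(2 * pi * 10 * t)
  df <- tibble::tibble(t = t, x = x)
  y <- lowpass_butterworth(df, spec)$x
  mid <- seq(200, length(t) - 200)
  gain <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_equal(gain, 0.5, tolerance = 0.02)
  # a 2 Hz passband component comes through with no phase shift
  x2 <- sin(2 * pi * 2 * t)
  y2 <- lowpass_butterworth(tibble::tibble(t = t, x = x2), spec)$x
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    idx <- mid
    stats::cor(x2[idx], y2[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("causal filtering delays the signal (motivating zero-phase)", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x2 <- sin(2 * pi * 2 * t)
  yc <- lowpass_butterworth(tibble::tibble(t = t, x = x2),
                            butter_spec(zero_phase = FALSE))$x
  lags <- 0:10
  mid <- seq(200, length(t) - 200)
  cc <- vapply(lags, function(l) stats::cor(x2[mid], yc[mid + l]), numeric(1))
  expect_gt(lags[which.max(cc)], 0)
})

test_that("filter rejects cutoffs at or above Nyquist", {
  df <- tibble::tibble(t = seq(0, 1, by = 0.1), x = rnorm(11))
  expect_error(lowpass_butterworth(df, butter_spec(cutoff = 6)), "Nyquist")
})

test_that("resample_to lands on the uniform target grid and rejects misuse", {
  fs_src <- 1259
  n <- round(12 * fs_src)
  t <- (seq_len(n) - 1) / fs_src
  df <- tibble::tibble(t = t, x = sin(2 * pi * 1.5 * t))
  out <- resample_to(df, 100)
  expect_equal(out$t, seq(0, by = 0.01, length.out = nrow(out)))
  expect_equal(nrow(out), 1200)
  # low-frequency content preserved through the anti-alias filter
  expect_equal(out$x[100:1100], sin(2 * pi * 1.5 * out$t[100:1100]),
               tolerance = 1e-2)
  expect_error(resample_to(out, 200), "Upsampling")
  df$x[5] <- NaN
  expect_error(resample_to(df, 100), "non-finite")
})

test_that("robust scaling centres by median and scales by IQR (type 7)", {
  set.seed(8)
  df <- tibble::tibble(t = seq(0, 9.99, by = 0.01),
                       a = rnorm(1000, 3, 2), b = rexp(1000))
  sc <- robust_scale(df)
  for (ch in c("a", "b")) {
    q <- quantile(df[[ch]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    expect_equal(sc[[ch]], (df[[ch]] - q[2]) / (q[3] - q[1]))
    expect_equal(median(sc[[ch]]), 0, tolerance = 1e-12)
    expect_equal(unname(diff(quantile(sc[[ch]], c(0.25, 0.75), type = 7))), 1,
                 tolerance = 1e-12)
  }
  p <- scaler_params(sc)
  expect_s3_class(p, "tbl_df")
  # applying stored params to new data uses the stored statistics
  df2 <- df
  df2$a <- df2$a + 100
  sc2 <- robust_scale(df2, params = p)
  expect_equal(sc2$a, sc$a + 100 / p$iqr[p$channel == "a"])
})

test_that("a constant channel is flagged degenerate with divisor 1", {
  df <- tibble::tibble(t = seq(0, 0.99, by = 0.01), a = rep(5, 100))
  sc <- robust_scale(df)
  expect_true(scaler_params(sc)$degenerate[1])
  expect_equal(sc$a, rep(0, 100))
})

test_that("segment_windows produces the documented layout", {
  fs <- 100
  n <- 1000
  df <- tibble::tibble(t = (seq_len(n) - 1) / fs,
                       a = seq_len(n), b = -seq_len(n))
  ws <- segment_windows(df, length = 0.2, hop = 0.1)
  n_samp <- 20
  expect_equal(nrow(ws$index), floor((n - n_samp) / 10) + 1)
  expect_equal(ws$index$start, (ws$index$window_id - 1) * 0.1)
  expect_equal(dim(ws$data), c(nrow(ws$index), 20, 2))
  # window k holds the contiguous slice starting at its start sample
  k <- 37
  s0 <- round(ws$index$start[k] * fs)
  expect_equal(ws$data[k, , 1], df$a[s0 + 1:20])
  expect_equal(ws$data[k, , 2], df$b[s0 + 1:20])
  expect_warning(segment_windows(df[1:5, ], length = 0.2, hop = 0.1),
                 "shorter")
})

test_that("label_windows marks exactly the windows whose centre band holds the event", {
  fs <- 100
  df <- tibble::tibble(t = (0:499) / fs, a = rnorm(500))
  ws <- segment_windows(df, length = 0.2, hop = 0.1)
  # event at 1.30 s: candidate windows start at 1.2 (band [1.29, 1.31] - hit)
  # and 1.3 (band [1.39, 1.41] - miss); window starting 1.1 has band
  # [1.19, 1.21] - miss
  ev <- tibble::tibble(time = 1.30, type = "HS", side = "R")
  lab <- label_windows(ws, ev)$labels
  hit <- which(lab$HS_R == 1)
  expect_equal(ws$index$start[hit], 1.2)
  expect_equal(sum(lab$HS_R), 1)
  expect_equal(sum(lab$HS_L) + sum(lab$TO_L) + sum(lab$TO_R), 0)

  # an event between bands labels no window at all: 1.25 s has offset 0.05
  # within every window, outside [0.09, 0.11] of any window start
  ev2 <- tibble::tibble(time = 1.25, type = "TO", side = "L")
  lab2 <- label_windows(ws, ev2)$labels
  expect_equal(sum(lab2$TO_L), 0)

  expect_error(label_windows(ws, ev, band = c(0.6, 0.4)), "increasing")
})

test_that("the narrow band labels at most one window per event, ~20% of events", {
  # With hop 0.1 s and band [0.45, 0.55] of a 0.2 s window, an event at time t
  # is captured iff (t mod 0.1) lies in [0, 0.01] or [0.09, 0.1): a 2/10
  # measure. Uniformly random events therefore label one window ~20% of the
  # time and zero windows otherwise - never two or more.
  fs <- 100
  df <- tibble::tibble(t = (0:2999) / fs, a = rnorm(3000))
  ws <- segment_windows(df, length = 0.2, hop = 0.1)
  set.seed(31)
  times <- sort(runif(400, 1, 28))
  hits <- vapply(times, function(tt) {
    lab <- label_windows(ws, tibble::tibble(time = tt, type = "HS",
                                            side = "R"))$labels
    sum(lab$HS_R)
  }, numeric(1))
  expect_true(all(hits <= 1))
  expect_gt(mean(hits), 0.12)
  expect_lt(mean(hits), 0.30)
})

test_that("prep_windows chains the preprocessing stages", {
  trial <- quick_trial(seed = 17, duration = 12)
  ev <- trial$events
  ws <- prep_windows(trial, ev)
  expect_s3_class(ws, "gait_windows")
  expect_equal(ws$rate, 100, tolerance = 1e-9)
  expect_equal(ws$length, 0.2)
  expect_equal(ws$hop, 0.1)
  expect_equal(dim(ws$data)[3], 6)
  expect_named(ws$labels, c("window_id", "HS_L", "HS_R", "TO_L", "TO_R"))
  expect_false(is.null(ws$scaler))
})
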