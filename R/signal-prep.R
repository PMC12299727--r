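# Resampling, filtering, robust scaling, windowing and window labeling of the
# IMU streams. Time series are tibbles with a time column `t` (seconds from
# trial start) and one column per channel.

#' Butterworth filter specification
#'
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 10).
#' @param zero_phase Apply forward-backward (zero group delay)? The default is
#'   `TRUE`: causal filtering would shift event signatures by tens of
#'   milliseconds and bias every event time. Note the effective attenuation is
#'   then applied twice, so the gain at the cutoff is 1/2 rather than
#'   1/sqrt(2).
#' @return A list of class `filter_spec`.
#' @export
butter_spec <- function(order = 4, cutoff = 10, zero_phase = TRUE) {
  check_scalar(order, "order")
  check_scalar(cutoff, "cutoff")
  structure(list(order = as.integer(order), cutoff = cutoff,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

channel_cols <- function(df) {
  setdiff(names(df)[vapply(df, is.numeric, logical(1))], "t")
}

#' Resample a uniform time series to a lower rate
#'
#' Applies an anti-alias low-pass filter (zero-phase Butterworth at 45% of the
#' target rate) and interpolates onto the uniform target grid
#' `t = 0, 1/rate, ...` covering `[0, duration)`. Non-integer rate ratios
#' (e.g. 1259 Hz to 100 Hz) are handled by the interpolation. Upsampling is
#' refused.
#'
#' @param df Tibble with column `t` and numeric channels, uniformly sampled.
#' @param target_rate Target rate in Hz.
#' @return Tibble on the target grid.
#' @export
resample_to <- function(df, target_rate) {
  check_scalar(target_rate, "target_rate")
  src_rate <- infer_rate(df$t)
  if (target_rate > src_rate * (1 + 1e-9)) {
    abort("Upsampling is not supported: `target_rate` exceeds the source rate.")
  }
  cols <- channel_cols(df)
  if (any(!is.finite(as.matrix(df[cols])))) {
    abort("Input contains non-finite samples.")
  }
  duration <- nrow(df) / src_rate
  t_out <- seq(0, by = 1 / target_rate,
               length.out = floor(duration * target_rate - 1e-9) + 1)
  t_out <- t_out[t_out < duration]
  if (target_rate < src_rate * (1 - 1e-9)) {
    aa <- signal::butter(4, (0.45 * target_rate) / (src_rate / 2))
    filt <- function(x) as.numeric(signal::filtfilt(aa, x))
  } else {
    filt <- identity
  }
  out <- lapply(df[cols], function(x) {
    approx(df$t, filt(x), xout = t_out, rule = 2)$y
  })
  as_tibble(c(list(t = t_out), out))
}

#' Low-pass Butterworth filter a time series
#'
#' @param df Tibble with column `t` and numeric channels.
#' @param spec A [butter_spec()]; the cutoff must be below the Nyquist rate.
#' @return Filtered tibble.
#' @export
lowpass_butterworth <- function(df, spec = butter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  rate <- infer_rate(df$t)
  if (spec$cutoff >= rate / 2) {
    abort("Filter cutoff must be below the Nyquist frequency.")
  }
  b <- signal::butter(spec$order, spec$cutoff / (rate / 2))
  cols <- channel_cols(df)
  # Forward-backward filtering starts each pass from unmatched initial
  # conditions, which rings for ~1/cutoff at both series ends and can fake
  # sample-scale extrema there. Odd (point-reflected) padding of three
  # cutoff periods moves those transients into the discarded pad.
  n <- nrow(df)
  pad <- min(n - 1L, as.integer(ceiling(3 * rate / spec$cutoff)))
  for (ch in cols) {
    x <- df[[ch]]
    df[[ch]] <- if (spec$zero_phase) {
      xp <- c(2 * x[1] - x[(pad + 1L):2],
              x,
              2 * x[n] - x[(n - 1L):(n - pad)])
      as.numeric(signal::filtfilt(b, xp))[(pad + 1L):(pad + n)]
    } else {
      as.numeric(signal::filter(b, x))
    }
  }
  df
}

#' Robust-scale channels (median / IQR)
#'
#' Per channel, subtracts the median and divides by the interquartile range
#' (linear-interpolation quartiles, `stats::quantile` type 7), limiting the
#' influence of outliers such as impact spikes. Channels with zero IQR are
#' centred and flagged degenerate (divisor 1).
#'
#' @param df Tibble with column `t` and numeric channels (>= 4 samples).
#' @param params Optional scaler tibble from a previous call, to apply a fitted
#'   scaling to new data.
#' @return Scaled tibble with the scaler parameters in attribute `"scaler"`
#'   (retrievable with [scaler_params()]).
#' @export
robust_scale <- function(df, params = NULL) {
  cols <- channel_cols(df)
  if (nrow(df) < 4) abort("Robust scaling needs at least 4 samples.")
  if (is.null(params)) {
    params <- purrr::map_dfr(cols, function(ch) {
      q <- quantile(df[[ch]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      raw_iqr <- q[3] - q[1]
      tibble(channel = ch, median = q[2],
             iqr = if (raw_iqr > 0) raw_iqr else 1,
             degenerate = raw_iqr <= 0)
    })
  }
  for (ch in cols) {
    p <- params[params$channel == ch, ]
    if (nrow(p) != 1) abort(sprintf("No scaler parameters for channel '%s'.", ch))
    df[[ch]] <- (df[[ch]] - p$median) / p$iqr
  }
  attr(df, "scaler") <- params
  df
}

#' @rdname robust_scale
#' @param x A tibble returned by [robust_scale()].
#' @export
scaler_params <- function(x) attr(x, "scaler")

#' Segment a time series into fixed, overlapping windows
#'
#' Windows of `length` seconds are placed at starts `0, hop, 2*hop, ...`; the
#' last window must lie fully inside the series (trailing partial windows are
#' dropped so every window has an identical sample shape).
#'
#' @param df Tibble with column `t` and numeric channels.
#' @param length Window length in seconds (default 0.200).
#' @param hop Hop between window starts in seconds (default 0.100, i.e. 50%
#'   overlap).
#' @return A `gait_windows` object: window index tibble, a
#'   `n_windows x samples x channels` array, and the segmentation metadata.
#' @export
segment_windows <- function(df, length = 0.2, hop = 0.1) {
  check_scalar(length, "length")
  check_scalar(hop, "hop")
  rate <- infer_rate(df$t)
  n <- nrow(df)
  n_samp <- round(length * rate)
  hop_samp <- max(1L, round(hop * rate))
  cols <- channel_cols(df)
  if (n < n_samp) {
    warn("Series shorter than one window; returning an empty window set.")
    starts_idx <- integer(0)
  } else {
    starts_idx <- seq(0L, n - n_samp, by = hop_samp)
  }
  nw <- base::length(starts_idx)
  data <- array(NA_real_, dim = c(nw, n_samp, base::length(cols)),
                dimnames = list(NULL, NULL, cols))
  if (nw > 0) {
    idx <- outer(starts_idx, seq_len(n_samp), "+")
    for (k in seq_along(cols)) data[, , k] <- df[[cols[k]]][idx]
  }
  structure(
    list(index = tibble(window_id = seq_len(nw), start = starts_idx / rate),
         data = data, channels = cols, rate = rate,
         length = n_samp / rate, hop = hop_samp / rate,
         labels = NULL, scaler = attr(df, "scaler")),
    class = "gait_windows"
  )
}

#' @export
print.gait_windows <- function(x, ...) {
  cat(sprintf("<gait_windows> %d windows of %.0f ms (hop %.0f ms), %d channels%s\n",
              nrow(x$index), 1000 * x$length, 1000 * x$hop,
              length(x$channels),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' Label windows by centred gait events
#'
#' A window is a positive example for an event stream (type x side) only if an
#' event of that stream falls near the window centre: between the `band[1]` and
#' `band[2]` fraction of the window length (inclusive on both ends; default the
#' 45th--55th percentile). This enforces accurate temporal localisation in the
#' trained detector.
#'
#' @param ws A `gait_windows` object.
#' @param events Event tibble with columns `time`, `type`, `side`.
#' @param band Length-2 fraction of the window length, inside `[0, 1]`.
#' @param streams Event streams to label (default all four).
#' @return `ws` with a `labels` tibble (`window_id`, one 0/1 column per
#'   stream).
#' @export
label_windows <- function(ws, events, band = c(0.45, 0.55),
                          streams = c("HS_L", "HS_R", "TO_L", "TO_R")) {
  if (base::length(band) != 2 || any(band < 0) || any(band > 1) ||
      band[1] > band[2]) {
    abort("`band` must be an increasing pair inside [0, 1].")
  }
  starts <- ws$index$start
  len <- ws$length
  lab <- tibble(window_id = ws$index$window_id)
  for (s in streams) {
    parts <- strsplit(s, "_", fixed = TRUE)[[1]]
    et <- events$time[events$type == parts[1] & events$side == parts[2]]
    if (base::length(et) == 0 || base::length(starts) == 0) {
      lab[[s]] <- rep(0L, base::length(starts))
      next
    }
    hit <- outer(starts + band[1] * len - 1e-9, et, "<=") &
      outer(starts + band[2] * len + 1e-9, et, ">=")
    lab[[s]] <- as.integer(rowSums(hit) > 0)
  }
  ws$labels <- lab
  ws
}

#' Prepare one trial's IMU stream for the window classifier
#'
#' Convenience chain implementing the standard preprocessing: downsample to
#' `rate`, zero-phase low-pass filter, robust-scale per channel (fitted on this
#' recording), segment into overlapping windows, and (optionally) label the
#' windows with reference events.
#'
#' @param trial A `gait_trial`.
#' @param events Optional event tibble used to label windows.
#' @param rate Analysis rate in Hz (default 100, the mocap rate).
#' @param spec Low-pass [butter_spec()].
#' @param length,hop,band Windowing parameters, see [segment_windows()] and
#'   [label_windows()].
#' @return A `gait_windows` object.
#' @export
prep_windows <- function(trial, events = NULL, rate = 100,
                         spec = butter_spec(), length = 0.2, hop = 0.1,
                         band = c(0.45, 0.55)) {
  ws <- trial$imu %>%
    resample_to(rate) %>%
    lowpass_butterworth(spec) %>%
    robust_scale() %>%
    segment_windows(length = length, hop = hop)
  if (!is.null(events)) ws <- label_windows(ws, events, band = band)
  ws
}
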