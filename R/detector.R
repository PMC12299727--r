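# Window-classifier event detector: subject-wise data split, per-stream
# training, window probability prediction, and reconstruction of continuous
# event times from supra-threshold window runs.

#' Detector architecture and training specification
#'
#' The default is a compact convolution + recurrent contract: two 1-D
#' convolution blocks (kernel 5, widths 16 and 32, each followed by max-pooling
#' by 2), an LSTM (32 units) over the pooled sequence, and a sigmoid head, one
#' independent model per event stream. Training minimises class-weighted binary
#' cross-entropy with Adam.
#'
#' @param conv_channels Integer vector of conv block widths.
#' @param kernel Odd kernel size shared by the conv blocks.
#' @param recurrent_units LSTM hidden size.
#' @param dropout Dropout fraction on the recurrent output during training.
#'   The default regularises against trial-specific carry orientations, which
#'   otherwise produce contralateral cross-talk on held-out trials.
#' @param epochs Training epochs (<= 30 for desk-scale runs).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param positive_class_weight Weight of the positive class in the loss;
#'   `NULL` (default) uses the negatives/positives ratio of the training fold
#'   (positive windows are rare, roughly 1 in 50).
#' @param val_fraction Fraction of training windows held out for the per-epoch
#'   precision/recall report.
#' @param seed Seed for initialisation, shuffling and dropout.
#' @return A list of class `detector_spec`.
#' @export
detector_spec <- function(conv_channels = c(16L, 32L), kernel = 5L,
                          recurrent_units = 32L, dropout = 0.2,
                          epochs = 14L, batch_size = 64L,
                          learning_rate = 1e-3,
                          positive_class_weight = NULL,
                          val_fraction = 0.1, seed = 1L) {
  stopifnot(all(conv_channels >= 1), kernel %% 2 == 1, recurrent_units >= 1,
            dropout >= 0, dropout < 1, epochs >= 0, batch_size >= 1,
            learning_rate > 0)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel),
                 recurrent_units = as.integer(recurrent_units),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 positive_class_weight = positive_class_weight,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "detector_spec")
}

#' Split a cohort into train and test subjects
#'
#' The split is at subject granularity: all trials of a subject fall on the
#' same side, so no subject leaks from training into evaluation.
#'
#' @param manifest Cohort manifest with a `subject` column.
#' @param fraction Training fraction (default 0.8).
#' @param seed Seed for the subject draw.
#' @return A list of class `split_plan` with `train_subjects` and
#'   `test_subjects`.
#' @export
split_by_subject <- function(manifest, fraction = 0.8, seed = 1L) {
  subjects <- sort(unique(manifest$subject))
  n <- length(subjects)
  if (n < 2) abort("Need at least 2 subjects to split.")
  n_train <- round(fraction * n)
  if (n_train < 1 || n_train >= n) {
    abort("`fraction` leaves an empty train or test set.")
  }
  set.seed(seed)
  train <- sort(sample(subjects, n_train))
  structure(list(train_subjects = train,
                 test_subjects = setdiff(subjects, train),
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

# stack labeled window sets into one array + label matrix
bind_window_sets <- function(window_sets, stream) {
  stopifnot(length(window_sets) >= 1)
  n_each <- vapply(window_sets, function(w) nrow(w$index), numeric(1))
  d1 <- dim(window_sets[[1]]$data)
  X <- array(NA_real_, dim = c(sum(n_each), d1[2], d1[3]))
  y <- integer(sum(n_each))
  at <- 0
  for (w in window_sets) {
    if (is.null(w$labels)) abort("Window sets must be labeled before training.")
    nw <- nrow(w$index)
    if (nw == 0) next
    X[at + seq_len(nw), , ] <- w$data
    y[at + seq_len(nw)] <- w$labels[[stream]]
    at <- at + nw
  }
  list(X = X, y = y)
}

weighted_bce <- function(p, y, w_pos) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-w_pos * y * log(p) - (1 - y) * log(1 - p))
}

#' Train an event-stream detector
#'
#' Trains one conv+LSTM window classifier for a single event stream (e.g.
#' `"HS_R"`) on labeled, robust-scaled windows. The loss is class-weighted
#' binary cross-entropy; with a fixed seed the loss trajectory is reproducible
#' on a single thread.
#'
#' @param window_sets List of labeled `gait_windows` (one per training trial),
#'   or a single `gait_windows`.
#' @param stream Event stream name: `"HS_L"`, `"HS_R"`, `"TO_L"` or `"TO_R"`.
#' @param spec A [detector_spec()].
#' @return A `gait_detector` with the trained parameters and a `report` tibble
#'   (per-epoch training loss and held-out window precision/recall).
#' @export
train_detector <- function(window_sets, stream, spec = detector_spec()) {
  if (inherits(window_sets, "gait_windows")) window_sets <- list(window_sets)
  dat <- bind_window_sets(window_sets, stream)
  if (length(unique(dat$y)) < 2) {
    abort("Training labels contain a single class; cannot train.")
  }
  n <- length(dat$y)
  S <- dim(dat$X)[2]; C <- dim(dat$X)[3]
  set.seed(spec$seed)
  n_val <- floor(spec$val_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  y_tr <- dat$y[train_idx]
  if (length(unique(y_tr)) < 2) {
    abort("Training fold lost one class in validation split; lower `val_fraction`.")
  }
  w_pos <- spec$positive_class_weight %||% (sum(y_tr == 0) / sum(y_tr == 1))

  params <- nn_init(C, S, spec)
  adam <- nn_adam_init(params)
  H <- spec$recurrent_units
  map_cache <- list()
  get_maps <- function(B) {
    key <- as.character(B)
    if (is.null(map_cache[[key]])) {
      map_cache[[key]] <<- nn_level_maps(S, B, spec)
    }
    map_cache[[key]]
  }

  report <- tibble(epoch = integer(0), loss = numeric(0),
                   val_precision = numeric(0), val_recall = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample(train_idx)
    loss_sum <- 0
    for (b0 in seq(1, length(ord), by = spec$batch_size)) {
      rows <- ord[b0:min(b0 + spec$batch_size - 1, length(ord))]
      B <- length(rows)
      A0 <- nn_batch_input(dat$X, rows)
      y_b <- dat$y[rows]
      drop_mask <- if (spec$dropout > 0) {
        matrix(stats::rbinom(H * B, 1, 1 - spec$dropout), H, B) /
          (1 - spec$dropout)
      } else NULL
      maps <- get_maps(B)
      fw <- nn_forward(params, A0, B, S, spec, maps, train = TRUE,
                       drop_mask = drop_mask)
      loss_sum <- loss_sum + weighted_bce(fw$p, y_b, w_pos) * B
      gr <- nn_backward(params, fw$cache, y_b, w_pos, B, spec, maps,
                        drop_mask = drop_mask)
      st <- nn_adam_step(params, gr, adam, spec$learning_rate)
      params <- st$params
      adam <- st$state
    }
    vp <- vr <- NA_real_
    if (length(val_idx)) {
      pv <- nn_predict(params, dat$X, val_idx, S, spec)
      pred <- pv >= 0.5
      truth <- dat$y[val_idx] == 1
      vp <- if (any(pred)) sum(pred & truth) / sum(pred) else NA_real_
      vr <- if (any(truth)) sum(pred & truth) / sum(truth) else NA_real_
    }
    report <- bind_rows(report, tibble(
      epoch = epoch, loss = loss_sum / length(ord),
      val_precision = vp, val_recall = vr))
  }
  structure(list(params = params, spec = spec, stream = stream,
                 n_samples = S, n_channels = C, class_weight = w_pos,
                 report = report),
            class = "gait_detector")
}

nn_predict <- function(params, X, rows, S, spec, chunk = 1024L) {
  out <- numeric(length(rows))
  for (b0 in seq(1, length(rows), by = chunk)) {
    sel <- rows[b0:min(b0 + chunk - 1, length(rows))]
    B <- length(sel)
    maps <- nn_level_maps(S, B, spec)
    A0 <- nn_batch_input(X, sel)
    out[b0:(b0 + B - 1)] <- nn_forward(params, A0, B, S, spec, maps)
  }
  out
}

#' Predict window probabilities
#'
#' @param detector A trained `gait_detector`.
#' @param ws A `gait_windows` whose shape matches the training windows.
#' @return Numeric vector of per-window probabilities in window order.
#' @export
predict_windows <- function(detector, ws) {
  d <- dim(ws$data)
  if (d[2] != detector$n_samples || d[3] != detector$n_channels) {
    abort("Window shape does not match the detector's training shape.")
  }
  if (d[1] == 0) return(numeric(0))
  nn_predict(detector$params, ws$data, seq_len(d[1]), detector$n_samples,
             detector$spec)
}

#' Reconstruct continuous event times from window probabilities
#'
#' Supra-threshold windows are grouped into runs of temporally adjacent
#' windows; each run becomes one candidate event at the confidence-weighted
#' mean of the run's window centres, with the run's maximum probability as its
#' confidence. Within any `refractory` span only the highest-confidence event
#' is kept (ties go to the earlier event).
#'
#' @param prob Window probabilities.
#' @param starts Window start times (temporal order, fixed hop).
#' @param length Window length in seconds.
#' @param threshold Detection threshold (default 0.5).
#' @param refractory Minimum spacing between events in seconds (default 0.4,
#'   the minimum plausible stride interval at walking speeds).
#' @return Tibble `time`, `confidence`, sorted by time (possibly empty).
#' @export
reconstruct_events <- function(prob, starts, length = 0.2, threshold = 0.5,
                               refractory = 0.4) {
  stopifnot(base::length(prob) == base::length(starts))
  keep <- which(prob >= threshold)
  if (!base::length(keep)) {
    return(tibble(time = numeric(0), confidence = numeric(0)))
  }
  hop <- if (base::length(starts) > 1) min(diff(starts)) else length
  grp <- cumsum(c(1, diff(keep) > 1 | diff(starts[keep]) > hop * 1.5))
  centers <- starts[keep] + length / 2
  cand <- tibble(grp = grp, p = prob[keep], center = centers) %>%
    group_by(.data$grp) %>%
    summarise(time = sum(.data$p * .data$center) / sum(.data$p),
              confidence = max(.data$p), .groups = "drop") %>%
    arrange(dplyr::desc(.data$confidence), .data$time)
  kept_t <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (all(abs(cand$time[i] - kept_t) >= refractory)) {
      kept_t <- c(kept_t, cand$time[i])
    }
  }
  cand %>%
    filter(.data$time %in% kept_t) %>%
    arrange(.data$time) %>%
    select("time", "confidence")
}

#' Detect events in a trial with a set of trained stream detectors
#'
#' @param detectors Named list of `gait_detector`s (names `HS_L`, `HS_R`,
#'   `TO_L`, `TO_R` or a subset).
#' @param ws The trial's `gait_windows`.
#' @param threshold,refractory See [reconstruct_events()].
#' @return Event tibble (`time`, `type`, `side`, `source = "model"`,
#'   `confidence`).
#' @export
detect_events <- function(detectors, ws, threshold = 0.5, refractory = 0.4) {
  out <- purrr::imap(detectors, function(det, nm) {
    prob <- predict_windows(det, ws)
    ev <- reconstruct_events(prob, ws$index$start, ws$length,
                             threshold, refractory)
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    mutate(ev, type = parts[1], side = parts[2], source = "model")
  })
  bind_rows(out) %>% arrange(.data$time)
}

#' @export
print.gait_detector <- function(x, ...) {
  last <- tail(x$report, 1)
  cat(sprintf("<gait_detector> stream %s | %d epochs | final loss %.4f\n",
              x$stream, nrow(x$report),
              if (nrow(x$report)) last$loss else NA))
  invisible(x)
}

#' @export
tidy.gait_detector <- function(x, ...) x$report

#' @export
glance.gait_detector <- function(x, ...) {
  last <- tail(x$report, 1)
  tibble(stream = x$stream, epochs = nrow(x$report),
         final_loss = if (nrow(x$report)) last$loss else NA_real_,
         val_precision = if (nrow(x$report)) last$val_precision else NA_real_,
         val_recall = if (nrow(x$report)) last$val_recall else NA_real_,
         class_weight = x$class_weight)
}
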