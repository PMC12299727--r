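# Window-classifier detector: data split, loss, training behaviour, window
# prediction and event-time reconstruction.

test_that("split_by_subject keeps all of a subject's trials on one side", {
  manifest <- tidyr::expand_grid(subject = sprintf("S%02d", 1:10),
                                 speed = c(1, 1.25, 1.5),
                                 placement = c("hand", "trouser", "jacket"))
  manifest$trial_id <- paste(manifest$subject, manifest$speed,
                             manifest$placement, sep = "_")
  sp <- split_by_subject(manifest, 0.8, seed = 5L)
  expect_s3_class(sp, "split_plan")
  expect_equal(length(sp$train_subjects), 8)
  expect_equal(length(sp$test_subjects), 2)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$test_subjects),
                  unique(manifest$subject))
  expect_identical(split_by_subject(manifest, 0.8, seed = 5L)$train_subjects,
                   sp$train_subjects)
  expect_error(split_by_subject(manifest[manifest$subject == "S01", ], 0.8, 1),
               "at least 2")
  expect_error(split_by_subject(manifest, 0.999, 1), "empty")
})

test_that("weighted BCE matches its formula", {
  p <- c(0.9, 0.2, 0.6)
  y <- c(1, 0, 1)
  w <- 3
  manual <- mean(c(-3 * log(0.9), -log(0.8), -3 * log(0.6)))
  expect_equal(gaitwin:::weighted_bce(p, y, w), manual)
  # clamping keeps the loss finite at p = 0 or 1
  expect_true(is.finite(gaitwin:::weighted_bce(c(0, 1), c(1, 0), 2)))
})

test_that("reconstruct_events merges runs, weights centres and applies refractory", {
  starts <- seq(0, 2, by = 0.1)
  prob <- rep(0, length(starts))
  # one run of three adjacent supra-threshold windows
  prob[5:7] <- c(0.6, 0.9, 0.7)  # starts 0.4, 0.5, 0.6; centres 0.5, 0.6, 0.7
  ev <- reconstruct_events(prob, starts, length = 0.2)
  manual <- sum(c(0.6, 0.9, 0.7) * c(0.5, 0.6, 0.7)) / sum(c(0.6, 0.9, 0.7))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, manual)
  expect_equal(ev$confidence, 0.9)

  # two separated runs: both kept (spacing > refractory)
  prob2 <- rep(0, length(starts))
  prob2[c(3, 15)] <- c(0.8, 0.7)
  ev2 <- reconstruct_events(prob2, starts, length = 0.2)
  expect_equal(ev2$time, c(0.3, 1.5))

  # two runs closer than the refractory: only the more confident survives
  prob3 <- rep(0, length(starts))
  prob3[c(3, 6)] <- c(0.55, 0.95)  # candidate events at 0.3 and 0.6 s
  ev3 <- reconstruct_events(prob3, starts, length = 0.2, refractory = 0.4)
  expect_equal(ev3$time, 0.6)
  expect_equal(ev3$confidence, 0.95)

  # threshold is inclusive; below-threshold everywhere gives an empty result
  expect_equal(nrow(reconstruct_events(rep(0.49, 5), starts[1:5], 0.2)), 0)
  ev4 <- reconstruct_events(c(0.5, 0, 0, 0, 0), starts[1:5], 0.2)
  expect_equal(nrow(ev4), 1)
})

test_that("an oracle detector reconstructs events within the 100 ms bound", {
  # the oracle marks every window that contains the event anywhere in its
  # span; the reconstructed time (weighted mean of window centres) can then be
  # off by at most half a window length
  set.seed(61)
  starts <- seq(0, 60, by = 0.1)
  len <- 0.2
  truth <- sort(runif(50, 1, 59))
  truth <- truth[c(TRUE, diff(truth) > 1)]
  prob <- vapply(starts, function(s) {
    as.numeric(any(truth >= s & truth <= s + len))
  }, numeric(1))
  ev <- reconstruct_events(prob, starts, len)
  expect_equal(nrow(ev), length(truth))
  for (tt in truth) {
    expect_lte(min(abs(ev$time - tt)), 0.100 + 1e-9)
  }
})

test_that("training needs labels and two classes", {
  trial <- quick_trial(seed = 41, duration = 12)
  ws <- prep_windows(trial)  # unlabeled
  expect_error(train_detector(ws, "HS_R"), "labeled")
  ws <- label_windows(ws, tibble::tibble(time = numeric(0),
                                         type = character(0),
                                         side = character(0)))
  expect_error(train_detector(ws, "HS_R"), "single class")
})

test_that("the detector learns a separable window task", {
  # synthetic windows: positives carry a centred bump on channel 1
  set.seed(71)
  n <- 400; S <- 20; C <- 2
  y <- rep(c(1L, 0L), n / 2)
  X <- array(rnorm(n * S * C, 0, 0.3), dim = c(n, S, C))
  bump <- exp(-((1:S) - 10.5)^2 / 4)
  for (i in which(y == 1)) X[i, , 1] <- X[i, , 1] + 2 * bump
  ws <- structure(list(index = tibble::tibble(window_id = 1:n,
                                              start = (0:(n - 1)) * 0.1),
                       data = X, channels = c("a", "b"), rate = 100,
                       length = 0.2, hop = 0.1,
                       labels = tibble::tibble(window_id = 1:n, HS_R = y),
                       scaler = NULL),
                  class = "gait_windows")
  # dropout off: this test checks that optimisation works on a cleanly
  # separable task, not regularisation behaviour
  spec <- detector_spec(conv_channels = c(8L, 8L), recurrent_units = 8L,
                        epochs = 10L, dropout = 0, seed = 9L)
  det <- train_detector(ws, "HS_R", spec)
  expect_s3_class(det, "gait_detector")
  expect_equal(nrow(det$report), 10)
  expect_lt(det$report$loss[10], det$report$loss[1])
  p <- predict_windows(det, ws)
  expect_gt(mean(p[y == 1]), mean(p[y == 0]) + 0.3)
  # tidy/glance accessors
  expect_identical(tidy(det), det$report)
  g <- glance(det)
  expect_equal(g$stream, "HS_R")
  expect_equal(g$epochs, 10)
  # training is reproducible from the spec seed
  det2 <- train_detector(ws, "HS_R", spec)
  expect_identical(det$report, det2$report)
  expect_equal(predict_windows(det2, ws), p)
})

test_that("predict_windows rejects mismatched window shapes", {
  set.seed(81)
  n <- 60; S <- 20
  y <- rep(c(1L, 0L), n / 2)
  X <- array(rnorm(n * S), dim = c(n, S, 1))
  for (i in which(y == 1)) X[i, 8:12, 1] <- X[i, 8:12, 1] + 2
  ws <- structure(list(index = tibble::tibble(window_id = 1:n,
                                              start = (0:(n - 1)) * 0.1),
                       data = X, channels = "a", rate = 100, length = 0.2,
                       hop = 0.1,
                       labels = tibble::tibble(window_id = 1:n, HS_R = y),
                       scaler = NULL),
                  class = "gait_windows")
  det <- train_detector(ws, "HS_R",
                        detector_spec(conv_channels = 4L,
                                      recurrent_units = 4L, epochs = 1L,
                                      val_fraction = 0, seed = 2L))
  bad <- ws
  bad$data <- array(0, dim = c(3, S + 4, 1))
  expect_error(predict_windows(det, bad), "shape")
})

test_that("detect_events assembles typed, sided model events", {
  set.seed(91)
  n <- 80; S <- 20
  y <- rep(c(1L, rep(0L, 7)), n / 8)
  X <- array(rnorm(n * S, 0, 0.2), dim = c(n, S, 1))
  bump <- exp(-((1:S) - 10.5)^2 / 4)
  for (i in which(y == 1)) X[i, , 1] <- X[i, , 1] + 3 * bump
  ws <- structure(list(index = tibble::tibble(window_id = 1:n,
                                              start = (0:(n - 1)) * 0.1),
                       data = X, channels = "a", rate = 100, length = 0.2,
                       hop = 0.1,
                       labels = tibble::tibble(window_id = 1:n, HS_R = y,
                                               TO_L = y),
                       scaler = NULL),
                  class = "gait_windows")
  spec <- detector_spec(conv_channels = 4L, recurrent_units = 4L,
                        epochs = 6L, val_fraction = 0, seed = 3L)
  dets <- list(HS_R = train_detector(ws, "HS_R", spec),
               TO_L = train_detector(ws, "TO_L", spec))
  ev <- detect_events(dets, ws)
  expect_setequal(unique(ev$source), "model")
  expect_true(all(ev$type %in% c("HS", "TO")))
  expect_true(all(ev$side %in% c("L", "R")))
  expect_equal(ev$time, sort(ev$time))
})
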