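# Per-cycle temporal gait parameters from any bilateral event stream (truth,
# marker or model), plus the cycle quality filter and condition-level
# aggregation.

# stance intervals of one side: each heel strike paired with the next toe-off;
# a leading toe-off opens a stance from -Inf, a trailing heel strike closes at
# +Inf
stance_intervals <- function(hs, to) {
  iv <- matrix(numeric(0), ncol = 2)
  if (length(to) && (!length(hs) || to[1] < hs[1])) {
    iv <- rbind(iv, c(-Inf, to[1]))
  }
  for (h in hs) {
    nxt <- to[to > h]
    iv <- rbind(iv, c(h, if (length(nxt)) nxt[1] else Inf))
  }
  iv
}

overlap_length <- function(iv, lo, hi) {
  if (!nrow(iv)) return(0)
  sum(pmax(0, pmin(iv[, 2], hi) - pmax(iv[, 1], lo)))
}

#' Compute per-cycle temporal parameters from bilateral events
#'
#' Each pair of consecutive ipsilateral heel strikes defines a gait cycle.
#' Stride time is the interval between the two heel strikes; stance time runs
#' from the heel strike to the next ipsilateral toe-off; swing time from that
#' toe-off to the closing heel strike; double-support time is the total time
#' within the cycle's stance during which the contralateral foot is also in
#' stance (interval intersection of the two sides' stance sets). Cycles without
#' an intervening ipsilateral toe-off are marked incomplete.
#'
#' @param events Tibble with columns `time`, `type` (`"HS"`/`"TO"`), `side`
#'   (`"L"`/`"R"`).
#' @return Tibble of class `cycle_params`: one row per cycle with `cycle_id`,
#'   `side`, `t_start`, `stride`, `stance`, `swing`, `double_support`, `valid`,
#'   `exclusion_reason`.
#' @export
compute_cycles <- function(events) {
  ev <- arrange(events, .data$time)
  sides <- list(
    L = list(hs = ev$time[ev$type == "HS" & ev$side == "L"],
             to = ev$time[ev$type == "TO" & ev$side == "L"]),
    R = list(hs = ev$time[ev$type == "HS" & ev$side == "R"],
             to = ev$time[ev$type == "TO" & ev$side == "R"])
  )
  rows <- list()
  for (s in c("L", "R")) {
    own <- sides[[s]]
    opp <- sides[[setdiff(c("L", "R"), s)]]
    opp_iv <- stance_intervals(opp$hs, opp$to)
    hs <- own$hs
    if (length(hs) < 2) next
    for (i in seq_len(length(hs) - 1)) {
      h0 <- hs[i]; h1 <- hs[i + 1]
      tos <- own$to[own$to > h0 & own$to < h1]
      if (!length(tos)) {
        rows[[length(rows) + 1]] <- tibble(
          side = s, t_start = h0, stride = h1 - h0, stance = NA_real_,
          swing = NA_real_, double_support = NA_real_, valid = FALSE,
          exclusion_reason = "incomplete")
        next
      }
      to1 <- tos[1]
      stance <- to1 - h0
      swing <- h1 - to1
      ds <- overlap_length(opp_iv, h0, to1)
      ok <- stance > 0 && swing > 0 && (h1 - h0) > 0 && ds >= 0 &&
        ds < (h1 - h0)
      rows[[length(rows) + 1]] <- tibble(
        side = s, t_start = h0, stride = h1 - h0, stance = stance,
        swing = swing, double_support = ds, valid = ok,
        exclusion_reason = if (ok) "none" else "negative_duration")
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(side = character(0), t_start = numeric(0), stride = numeric(0),
           stance = numeric(0), swing = numeric(0),
           double_support = numeric(0), valid = logical(0),
           exclusion_reason = character(0))
  out <- arrange(out, .data$t_start) %>%
    mutate(cycle_id = dplyr::row_number(), .before = 1)
  class(out) <- c("cycle_params", class(out))
  out
}

#' Quality-filter gait cycles
#'
#' Excludes cycles with any negative duration, cycles whose span contains a
#' condition transition, and cycles with implausible stride times. Reasons are
#' assigned in that order of precedence and tallied.
#'
#' @param cycles A [compute_cycles()] tibble.
#' @param transitions Numeric vector of condition-transition timestamps.
#' @param stride_bounds Plausible stride-time range in seconds (default
#'   `c(0.4, 2.5)`).
#' @return The cycles tibble with updated `valid`/`exclusion_reason` and an
#'   attribute `"exclusion_tally"` (tibble reason/n).
#' @export
filter_cycles <- function(cycles, transitions = numeric(0),
                          stride_bounds = c(0.4, 2.5)) {
  reason <- cycles$exclusion_reason
  valid <- cycles$valid
  neg <- !is.na(cycles$stance) &
    (cycles$stance < 0 | cycles$swing < 0 | cycles$stride < 0 |
       cycles$double_support < 0)
  spans_transition <- function(t0, t1) {
    any(transitions >= t0 & transitions < t1)
  }
  trans <- purrr::map2_lgl(cycles$t_start, cycles$t_start + cycles$stride,
                           spans_transition)
  impl <- cycles$stride < stride_bounds[1] | cycles$stride > stride_bounds[2]
  set <- function(cond, label) {
    hit <- cond & valid
    reason[hit] <<- label
    valid[hit] <<- FALSE
  }
  set(neg, "negative_duration")
  set(trans, "transition")
  set(impl, "implausible")
  cycles$valid <- valid
  cycles$exclusion_reason <- reason
  reasons <- c("negative_duration", "transition", "implausible", "incomplete")
  n_excl <- vapply(reasons, function(r) sum(reason == r & !valid), numeric(1))
  tally <- tibble(reason = reasons, n = unname(n_excl))
  attr(cycles, "exclusion_tally") <- tally
  cycles
}

#' Left/right symmetry index
#'
#' Normalised absolute difference of side means, in percent:
#' `100 * |mean(R) - mean(L)| / (0.5 * (mean(R) + mean(L)))`.
#'
#' @param left,right Numeric vectors of per-cycle values (both non-empty).
#' @return Percentage.
#' @export
symmetry_index <- function(left, right) {
  if (!length(left) || !length(right)) {
    abort("Both sides must be non-empty for a symmetry index.")
  }
  ml <- mean(left); mr <- mean(right)
  100 * abs(mr - ml) / (0.5 * (mr + ml))
}

#' Aggregate valid cycles into condition-level parameter means
#'
#' One mean per subject x speed x placement and parameter, pooling left and
#' right sides. Conditions without valid cycles are omitted with a warning.
#'
#' @param cycles Cycle tibble carrying a `trial_id` column.
#' @param manifest Cohort manifest (`trial_id`, `subject`, `speed`,
#'   `placement`).
#' @return Long tibble `subject`, `speed`, `placement`, `parameter`, `mean`,
#'   `n_cycles`.
#' @export
aggregate_by_condition <- function(cycles, manifest) {
  dat <- cycles %>%
    filter(.data$valid) %>%
    left_join(manifest %>% select("trial_id", "subject", "speed", "placement"),
              by = "trial_id")
  if (!nrow(dat)) {
    warn("No valid cycles to aggregate.")
  }
  out <- dat %>%
    tidyr::pivot_longer(c("stride", "stance", "swing", "double_support"),
                        names_to = "parameter", values_to = "value") %>%
    group_by(.data$subject, .data$speed, .data$placement, .data$parameter) %>%
    summarise(mean = mean(.data$value), n_cycles = dplyr::n(),
              .groups = "drop")
  n_cond <- nrow(distinct(manifest, .data$subject, .data$speed,
                          .data$placement))
  n_here <- nrow(distinct(out, .data$subject, .data$speed, .data$placement))
  if (n_here < n_cond) {
    warn(sprintf("%d condition(s) without valid cycles were omitted.",
                 n_cond - n_here))
  }
  out
}
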