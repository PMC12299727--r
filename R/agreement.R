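# Agreement battery between experimental (M1, marker-based) and predicted
# (M2, model-based) gait parameters: cycle matching, relative RMSE with
# bootstrap summaries, Pearson association tiers and Bland-Altman analysis.

#' Match predicted cycles to experimental cycles
#'
#' Greedy nearest-heel-strike matching within `tolerance`, per side: pairs are
#' taken in order of increasing start-time difference, each cycle is used at
#' most once, and unmatched cycles are dropped and counted.
#'
#' @param m1,m2 Cycle tibbles ([compute_cycles()]) from the same trial.
#' @param tolerance Maximum heel-strike time difference in seconds.
#' @return Tibble of paired cycles (`side`, `t_start_m1`, `t_start_m2`, and
#'   `<param>_m1`/`<param>_m2` columns) with attribute `"unmatched"`
#'   (list m1/m2 counts).
#' @export
match_cycles <- function(m1, m2, tolerance = 0.25) {
  params <- c("stride", "stance", "swing", "double_support")
  out <- list()
  un_m1 <- 0; un_m2 <- 0
  for (s in unique(c(m1$side, m2$side))) {
    a <- m1[m1$side == s & m1$valid, ]
    b <- m2[m2$side == s & m2$valid, ]
    if (!nrow(a) || !nrow(b)) {
      un_m1 <- un_m1 + nrow(a); un_m2 <- un_m2 + nrow(b)
      next
    }
    d <- abs(outer(a$t_start, b$t_start, "-"))
    ord <- order(d)
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    pairs <- list()
    for (k in ord) {
      if (d[k] > tolerance) break
      i <- (k - 1) %% nrow(a) + 1
      j <- (k - 1) %/% nrow(a) + 1
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
    un_m1 <- un_m1 + sum(!used_a); un_m2 <- un_m2 + sum(!used_b)
    if (!length(pairs)) next
    pm <- do.call(rbind, pairs)
    row <- tibble(side = s, t_start_m1 = a$t_start[pm[, 1]],
                  t_start_m2 = b$t_start[pm[, 2]])
    for (p in params) {
      row[[paste0(p, "_m1")]] <- a[[p]][pm[, 1]]
      row[[paste0(p, "_m2")]] <- b[[p]][pm[, 2]]
    }
    out[[s]] <- row
  }
  res <- if (length(out)) bind_rows(out) %>% arrange(.data$t_start_m1) else
    tibble(side = character(0), t_start_m1 = numeric(0),
           t_start_m2 = numeric(0))
  attr(res, "unmatched") <- list(m1 = un_m1, m2 = un_m2)
  res
}

#' Relative root mean square error
#'
#' `100 * sqrt(mean((m2 - m1)^2)) / mean(m1)`, in percent; the denominator is
#' the mean of the experimental (reference) series.
#'
#' The evaluation order is pinned to single-pass `sum()`-based reductions so
#' that an independent recomputation of the same convention reproduces the
#' result bit for bit (base [mean()] adds a centering correction pass that
#' shifts the last ulp).
#'
#' @param m1 Experimental values (mean must be positive).
#' @param m2 Predicted values (same length).
#' @return Percentage.
#' @export
rrmse <- function(m1, m2) {
  if (!length(m1) || length(m1) != length(m2)) {
    abort("`m1` and `m2` must be non-empty vectors of equal length.")
  }
  n <- length(m1)
  mu1 <- sum(m1) / n
  if (mu1 <= 0) abort("`mean(m1)` must be positive.")
  100 * sqrt(sum((m2 - m1)^2) / n) / mu1
}

#' Summarise a sample of rRMSE values
#'
#' Median and IQR by the linear-interpolation quartile convention, a percentile
#' bootstrap 95% confidence interval of the mean (so that, under right skew,
#' the median can fall below the CI lower bound), and Fisher-Pearson g1
#' skewness.
#'
#' @param values Per-subject rRMSE values.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return One-row tibble `median`, `iqr`, `ci_low`, `ci_high`, `skewness`,
#'   `n`, `ci_ok` (FALSE when fewer than 3 values).
#' @export
summarize_rrmse <- function(values, n_boot = 1000, seed = 1L) {
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  ci <- c(NA_real_, NA_real_)
  ok <- length(values) >= 3
  if (ok) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(sample(values, replace = TRUE))
    }, numeric(1))
    ci <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  }
  tibble(median = q[2], iqr = q[3] - q[1], ci_low = ci[1], ci_high = ci[2],
         skewness = if (length(values) >= 3 && sd(values) > 0)
           e1071::skewness(values, type = 1) else NA_real_,
         n = length(values), ci_ok = ok)
}

#' Pearson association with strength tier
#'
#' Sample Pearson correlation with a two-sided t-test p-value, tiered by the
#' conventional thresholds: weak (r < 0.3), moderate (0.3 <= r < 0.6), strong
#' (r >= 0.6).
#'
#' As with [rrmse()], the arithmetic is pinned to the explicit product-moment
#' formula with single-pass `sum()` reductions (equal to [cor.test()] up to
#' the last ulp) so independent recomputation is bit-for-bit reproducible.
#'
#' @param m1,m2 Paired condition-level means (n >= 3, nonzero variance).
#' @return One-row tibble `r`, `p_value`, `tier`, `n`.
#' @export
pearson_association <- function(m1, m2) {
  if (length(m1) != length(m2) || length(m1) < 3) {
    abort("Need at least 3 paired values.")
  }
  if (sd(m1) == 0 || sd(m2) == 0) abort("Zero variance in one of the series.")
  n <- length(m1)
  mx <- sum(m1) / n
  my <- sum(m2) / n
  r <- sum((m1 - mx) * (m2 - my)) /
    (sqrt(sum((m1 - mx)^2)) * sqrt(sum((m2 - my)^2)))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble(r = r, p_value = p_value,
         tier = dplyr::case_when(r < 0.3 ~ "weak",
                                 r < 0.6 ~ "moderate",
                                 TRUE ~ "strong"),
         n = n)
}

#' Bland-Altman agreement
#'
#' Differences are oriented experimental minus predicted (M1 - M2); the bias is
#' their mean and the 95% limits of agreement are bias +/- 1.96 sample SD.
#' Points exactly on a limit count as within. The arithmetic is pinned to
#' single-pass `sum()`-based reductions (see [rrmse()]) so independent
#' recomputation is bit-for-bit reproducible.
#'
#' @param m1,m2 Paired values (n >= 2).
#' @return A one-row tibble of class `bland_altman`: `bias`, `loa_low`,
#'   `loa_high`, `pct_within`, `n`, plus the paired data in attribute
#'   `"points"`.
#' @export
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2) || length(m1) < 2) {
    abort("Need at least 2 paired values.")
  }
  d <- m1 - m2
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  out <- tibble(bias = bias, loa_low = loa_low, loa_high = loa_high,
                pct_within = 100 * sum(d >= loa_low & d <= loa_high) / n,
                n = n)
  attr(out, "points") <- tibble(mean = (m1 + m2) / 2, diff = d)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Build the full agreement report
#'
#' Combines matched per-cycle values and condition-level means into the three
#' standard tables: per-condition rRMSE summaries, Pearson association tiers,
#' and Bland-Altman bias/limits per parameter and placement, plus pooled
#' (all-condition) rows labelled `"all"`.
#'
#' @param cycle_rrmse Tibble `subject`, `speed`, `placement`, `parameter`,
#'   `rrmse` (one value per subject-condition, from matched cycles).
#' @param means_m1,means_m2 Condition-mean tibbles from
#'   [aggregate_by_condition()] for the experimental and predicted pipelines.
#' @param n_boot,seed Bootstrap settings for [summarize_rrmse()].
#' @return A list of class `agreement_report`: `rrmse_table`, `pearson_table`,
#'   `bland_altman_table`, `paired_means`.
#' @export
build_report <- function(cycle_rrmse, means_m1, means_m2, n_boot = 1000,
                         seed = 1L) {
  rrmse_table <- cycle_rrmse %>%
    group_by(.data$parameter, .data$speed, .data$placement) %>%
    dplyr::group_modify(~ summarize_rrmse(.x$rrmse, n_boot, seed)) %>%
    ungroup()

  paired <- dplyr::inner_join(
    means_m1 %>% rename(m1 = "mean"),
    means_m2 %>% rename(m2 = "mean"),
    by = c("subject", "speed", "placement", "parameter")
  )

  safe_pearson <- function(df) {
    tryCatch(pearson_association(df$m1, df$m2),
             error = function(e) tibble(r = NA_real_, p_value = NA_real_,
                                        tier = NA_character_, n = nrow(df)))
  }
  pearson_cond <- paired %>%
    group_by(.data$parameter, .data$speed, .data$placement) %>%
    dplyr::group_modify(~ safe_pearson(.x)) %>%
    ungroup()
  pearson_all <- paired %>%
    group_by(.data$parameter) %>%
    dplyr::group_modify(~ safe_pearson(.x)) %>%
    ungroup() %>%
    mutate(speed = NA_real_, placement = "all")

  ba_fun <- function(df) {
    tryCatch(as_tibble(bland_altman(df$m1, df$m2)),
             error = function(e) tibble(bias = NA_real_, loa_low = NA_real_,
                                        loa_high = NA_real_,
                                        pct_within = NA_real_,
                                        n = nrow(df)))
  }
  ba_cond <- paired %>%
    group_by(.data$parameter, .data$placement) %>%
    dplyr::group_modify(~ ba_fun(.x)) %>%
    ungroup()
  ba_all <- paired %>%
    group_by(.data$parameter) %>%
    dplyr::group_modify(~ ba_fun(.x)) %>%
    ungroup() %>%
    mutate(placement = "all")

  structure(list(rrmse_table = rrmse_table,
                 pearson_table = bind_rows(pearson_cond, pearson_all),
                 bland_altman_table = bind_rows(ba_cond, ba_all),
                 paired_means = paired),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n  rRMSE rows:", nrow(x$rrmse_table),
      "| Pearson rows:", nrow(x$pearson_table),
      "| Bland-Altman rows:", nrow(x$bland_altman_table), "\n")
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  bind_rows(
    x$rrmse_table %>% mutate(statistic = "rrmse"),
    x$pearson_table %>% mutate(statistic = "pearson"),
    x$bland_altman_table %>% mutate(statistic = "bland_altman")
  )
}

#' @export
glance.agreement_report <- function(x, ...) {
  stride <- x$rrmse_table %>% filter(.data$parameter == "stride")
  # Bland-Altman analyses live at parameter x placement granularity (one
  # analysis per plot, points = subject x speed); the headline coverage is
  # the share of all points inside their own analysis' limits
  ba_pp <- x$bland_altman_table %>%
    filter(.data$placement != "all", !is.na(.data$pct_within))
  pe_all <- x$pearson_table %>%
    filter(.data$placement == "all", .data$parameter == "stride")
  tibble(
    stride_rrmse_median = median(stride$median),
    pct_within_loa = sum(ba_pp$pct_within * ba_pp$n) / sum(ba_pp$n),
    stride_pearson_r = if (nrow(pe_all)) pe_all$r[1] else NA_real_
  )
}

#' Write the report tables as CSV files
#'
#' @param report An `agreement_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$rrmse_table, file.path(dir, "table1_rrmse.csv"))
  readr::write_csv(report$pearson_table, file.path(dir, "table2_pearson.csv"))
  readr::write_csv(report$bland_altman_table,
                   file.path(dir, "bland_altman.csv"))
  readr::write_csv(report$paired_means, file.path(dir, "condition_means.csv"))
  invisible(dir)
}
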