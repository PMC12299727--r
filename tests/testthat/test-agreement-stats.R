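# Agreement battery: rRMSE, bootstrap summaries, Pearson tiers, Bland-Altman
# and cycle matching, all checked against brute-force recomputations.

test_that("rrmse matches its worked examples and brute force", {
  expect_equal(rrmse(c(1, 1), c(1.05, 0.95)), 5.0)
  expect_equal(rrmse(c(2, 3, 4), c(2, 3, 4)), 0)
  set.seed(101)
  m1 <- runif(20, 0.9, 1.3)
  m2 <- m1 + rnorm(20, 0, 0.05)
  expect_identical(rrmse(m1, m2), brute_rrmse(m1, m2))
  # scale invariance
  expect_equal(rrmse(3 * m1, 3 * m2), rrmse(m1, m2))
  expect_error(rrmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rrmse(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(rrmse(c(-1, -1), c(1, 1)), "positive")
})

test_that("summarize_rrmse follows the fixed conventions", {
  s <- summarize_rrmse(rep(10, 5), n_boot = 200, seed = 4L)
  expect_equal(s$median, 10)
  expect_equal(s$iqr, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(10, 10))

  # right-skewed sample: the median falls below the mean's bootstrap CI
  # (needs mean - median > ~2 SD/sqrt(n); a tiny sample like {1,1,1,1,20}
  # cannot show it because >2.5% of bootstrap resamples miss the outlier)
  set.seed(7)
  v <- round(rexp(60), 3)
  s2 <- summarize_rrmse(v, n_boot = 1000, seed = 4L)
  expect_equal(s2$median, unname(quantile(v, 0.5, type = 7)))
  expect_lt(s2$median, s2$ci_low)
  expect_gt(s2$skewness, 0)
  # g1 skewness, Fisher-Pearson (e1071 type 1)
  g1 <- mean((v - mean(v))^3) / (mean((v - mean(v))^2))^1.5
  expect_equal(s2$skewness, g1, tolerance = 1e-12)
  # quartiles by the linear-interpolation (type 7) convention
  v3 <- c(1, 2, 4, 8, 16, 32)
  s3 <- summarize_rrmse(v3, n_boot = 50, seed = 1L)
  expect_equal(s3$median, unname(quantile(v3, 0.5, type = 7)))
  expect_equal(s3$iqr, unname(diff(quantile(v3, c(0.25, 0.75), type = 7))))
  # same seed, same CI; different seed, (almost surely) different CI
  s4 <- summarize_rrmse(v, n_boot = 1000, seed = 4L)
  expect_identical(s2, s4)
  # fewer than 3 values: CI omitted and flagged
  s5 <- summarize_rrmse(c(3, 5), seed = 1L)
  expect_false(s5$ci_ok)
  expect_true(is.na(s5$ci_low))
})

test_that("pearson_association matches cor.test and the tier thresholds", {
  m1 <- c(1.0, 1.1, 1.3, 1.5, 1.8)
  expect_equal(pearson_association(m1, 2 * m1 + 1)$r, 1)
  expect_equal(pearson_association(m1, 2 * m1 + 1)$tier, "strong")
  expect_equal(pearson_association(m1, -m1)$r, -1)
  expect_equal(pearson_association(m1, -m1)$tier, "weak")
  set.seed(11)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pa <- pearson_association(x, y)
  bf <- brute_pearson(x, y)
  expect_equal(pa$r, bf$r)
  expect_equal(pa$p_value, bf$p)
  ct <- cor.test(x, y)
  expect_equal(pa$r, unname(ct$estimate))
  expect_equal(pa$p_value, ct$p.value)
  # tier boundaries: r < 0.3 weak, r < 0.6 moderate, r >= 0.6 strong
  tier_of <- function(r) {
    # construct a pair with exactly the requested correlation via rotation
    n <- 100
    set.seed(5)
    a <- scale(rnorm(n))[, 1]
    b <- scale(stats::resid(lm(rnorm(n) ~ a)))[, 1]
    y <- r * a + sqrt(1 - r^2) * b
    pearson_association(a, y)$tier
  }
  expect_equal(tier_of(0.29), "weak")
  expect_equal(tier_of(0.45), "moderate")
  expect_equal(tier_of(0.65), "strong")
  expect_error(pearson_association(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_association(1:2, 2:3), "at least 3")
})

test_that("bland_altman matches its worked example and brute force", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$pct_within, 100)

  # d = {0.01, 0.03}: bias 0.02, loa ~ [-0.00772, 0.04772]
  ba <- bland_altman(c(1.01, 1.03), c(1, 1))
  expect_equal(ba$bias, 0.02)
  expect_equal(ba$loa_low, 0.02 - 1.96 * sd(c(0.01, 0.03)), tolerance = 1e-12)
  expect_equal(ba$loa_low, -0.00772, tolerance = 1e-3)
  expect_equal(ba$loa_high, 0.04772, tolerance = 1e-3)

  set.seed(21)
  m1 <- rnorm(200, 1, 0.1); m2 <- m1 + rnorm(200, 0.02, 0.03)
  got <- bland_altman(m1, m2)
  bf <- brute_bland_altman(m1, m2)
  expect_equal(got$bias, bf$bias)
  expect_equal(got$loa_low, bf$loa_low)
  expect_equal(got$loa_high, bf$loa_high)
  expect_equal(got$pct_within, bf$pct_within)
  # differences are oriented M1 - M2
  expect_lt(got$bias, 0)
  # Gaussian differences land near the nominal 95%
  expect_gt(got$pct_within, 93)
  expect_lt(got$pct_within, 97.5)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("match_cycles pairs nearest starts within tolerance, once each", {
  mk <- function(t_start, side = "R") tibble::tibble(
    cycle_id = seq_along(t_start), side = side, t_start = t_start,
    stride = 1, stance = 0.6, swing = 0.4, double_support = 0.15,
    valid = TRUE, exclusion_reason = "none")
  m1 <- mk(c(1.0, 2.0, 3.0))
  m2 <- mk(c(1.05, 2.30, 5.0))  # 2.30 is within 0.25 of neither? |2.3-2.0|=0.3
  res <- match_cycles(m1, m2, tolerance = 0.25)
  expect_equal(nrow(res), 1)
  expect_equal(res$t_start_m1, 1.0)
  expect_equal(res$t_start_m2, 1.05)
  un <- attr(res, "unmatched")
  expect_equal(un$m1, 2)
  expect_equal(un$m2, 2)
  # greedy: each cycle used at most once, closest pair wins
  m2b <- mk(c(1.02, 2.08))
  res2 <- match_cycles(m1, m2b, tolerance = 0.25)
  expect_equal(nrow(res2), 2)
  expect_equal(res2$t_start_m2[res2$t_start_m1 == 1.0], 1.02)
  expect_equal(res2$t_start_m2[res2$t_start_m1 == 2.0], 2.08)
  # invalid cycles never match
  m2c <- mk(1.0)
  m2c$valid <- FALSE
  expect_equal(nrow(match_cycles(m1, m2c, 0.25)), 0)
  # sides are matched independently
  res3 <- match_cycles(dplyr::bind_rows(mk(1), mk(1.01, "L")),
                       dplyr::bind_rows(mk(1.02), mk(0.99, "L")), 0.25)
  expect_equal(nrow(res3), 2)
  expect_setequal(res3$side, c("L", "R"))
})

test_that("build_report assembles the three tables with pooled rows", {
  set.seed(31)
  grid <- tidyr::expand_grid(subject = c("S01", "S02", "S03", "S04"),
                             speed = c(1, 1.25), placement = c("hand", "jacket"),
                             parameter = c("stride", "stance"))
  cycle_rrmse <- grid %>%
    dplyr::distinct(subject, speed, placement, parameter) %>%
    dplyr::mutate(rrmse = runif(dplyr::n(), 1, 6), n_pairs = 30)
  base <- grid %>% dplyr::mutate(mean = runif(dplyr::n(), 0.5, 1.4),
                                 n_cycles = 40)
  m2 <- base %>% dplyr::mutate(mean = mean + rnorm(dplyr::n(), 0, 0.02))
  rep <- build_report(cycle_rrmse, base, m2, n_boot = 100, seed = 7L)
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep$rrmse_table), 2 * 2 * 2)  # parameter x speed x placement
  # pooled rows present
  expect_true(all(c("hand", "jacket", "all") %in% rep$bland_altman_table$placement))
  expect_true("all" %in% rep$pearson_table$placement)
  # bland-altman rows reproducible by brute force from the paired means
  pm <- rep$paired_means
  for (p in unique(pm$parameter)) {
    sub <- pm[pm$parameter == p, ]
    bf <- brute_bland_altman(sub$m1, sub$m2)
    row <- rep$bland_altman_table[rep$bland_altman_table$parameter == p &
                                    rep$bland_altman_table$placement == "all", ]
    expect_equal(row$bias, bf$bias)
    expect_equal(row$loa_low, bf$loa_low)
    expect_equal(row$pct_within, bf$pct_within)
  }
  # glance exposes the three headline quantities
  g <- glance(rep)
  expect_named(g, c("stride_rrmse_median", "pct_within_loa",
                    "stride_pearson_r"))
  expect_true(all(is.finite(unlist(g))))
  # tidy stacks the tables
  td <- tidy(rep)
  expect_true(all(c("rrmse", "pearson", "bland_altman") %in% td$statistic))
  # identical inputs and seed give identical tables
  rep2 <- build_report(cycle_rrmse, base, m2, n_boot = 100, seed = 7L)
  expect_identical(rep$rrmse_table, rep2$rrmse_table)
})

test_that("write_report emits the four CSV tables", {
  set.seed(41)
  cycle_rrmse <- tidyr::expand_grid(subject = c("S01", "S02", "S03"),
                                    speed = 1.25, placement = "hand",
                                    parameter = "stride") %>%
    dplyr::mutate(rrmse = runif(3, 1, 4), n_pairs = 20)
  means <- tidyr::expand_grid(subject = c("S01", "S02", "S03"), speed = 1.25,
                              placement = "hand",
                              parameter = c("stride", "stance")) %>%
    dplyr::mutate(mean = runif(6, 0.5, 1.3), n_cycles = 30)
  m2 <- means %>% dplyr::mutate(mean = mean + 0.01)
  rep <- build_report(cycle_rrmse, means, m2, n_boot = 50, seed = 2L)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_setequal(list.files(dir),
                  c("table1_rrmse.csv", "table2_pearson.csv",
                    "bland_altman.csv", "condition_means.csv"))
  back <- readr::read_csv(file.path(dir, "bland_altman.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep$bland_altman_table))
})
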