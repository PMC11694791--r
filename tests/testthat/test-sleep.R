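test_that("the zero-count sleep rule is applied literally", {
  pir <- activity_record(c(0, 3, 0, 0, 1), 1, channel = "pir")
  sl <- pir_to_sleep(pir)
  expect_equal(sl$minutes, c(1, 0, 1, 1, 0))

  # masked minutes stay masked
  pm <- activity_record(c(0, 3, NA, 0), 1, channel = "pir")
  expect_true(is.na(pir_to_sleep(pm)$minutes[3]))

  # an all-zero day is 1440 sleep minutes
  allz <- activity_record(rep(0, 1440), 1, channel = "pir")
  expect_equal(sum(pir_to_sleep(allz)$minutes), 1440)

  expect_error(pir_to_sleep(activity_record(1:10, 5, channel = "pir")),
               "1-min")
  expect_error(pir_to_sleep(activity_record(1:10, 1, channel = "wheel")),
               "pir")
})

test_that("sleep plus wake minutes always equal unmasked minutes", {
  for (seed in 1:10) {
    pir <- simulate_pir_sleepwake(sleep_pattern_spec(seed = seed), days = 4)
    sl <- pir_to_sleep(pir)
    ok <- !sl$gap_mask
    expect_equal(sum(sl$minutes[ok] == 1) + sum(sl$minutes[ok] == 0), sum(ok))
  }
})

test_that("day labeling orders by sleep and flips under a 24-h shift", {
  # two-day forced ordering: 500 vs 1000 sleep minutes
  m <- c(rep(c(0, 1), c(940, 500)), rep(c(0, 1), c(440, 1000)))
  pir <- activity_record(ifelse(m == 1, 0, 2), 1, channel = "pir")
  sl <- pir_to_sleep(pir)
  lab <- label_days(sl, time_window(0, 48))
  expect_equal(lab$labels, c("active", "inactive"))

  # 4 days alternating; shifting the window start by 24 h flips all labels
  pir4 <- simulate_pir_sleepwake(sleep_pattern_spec(seed = 2), days = 6)
  sl4 <- pir_to_sleep(pir4)
  l0 <- label_days(sl4, time_window(0, 96))
  l1 <- label_days(sl4, time_window(24, 96))
  expect_true(all(l0$labels != l1$labels))

  # all-equal daily sleep is ambiguous
  flat <- activity_record(rep(c(0, 2), 2 * 1440), 1, channel = "pir")
  expect_error(label_days(pir_to_sleep(flat), time_window(0, 96)),
               "ambiguous")
})

test_that("programmed alternation is recovered on almost all days", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    pir <- simulate_pir_sleepwake(sleep_pattern_spec(seed = seed), days = 8)
    lab <- label_days(pir_to_sleep(pir), time_window(0, 8 * 24))
    truth <- rep(c("active", "inactive"), 4)
    hits <- hits + sum(lab$labels == truth)
    total <- total + 8
  }
  expect_gte(hits / total, 0.95)
})

test_that("the selected window falls inside the cycling epoch", {
  for (seed in 1:3) {
    set.seed(seed)
    pre <- activity_record(rpois(9 * 1440, 3) + 1, 1, channel = "pir")
    cyc <- simulate_pir_sleepwake(sleep_pattern_spec(seed = seed), days = 12)
    post <- activity_record(rpois(3 * 1440, 3) + 1, 1, channel = "pir")
    rec <- activity_record(c(pre$counts, cyc$counts, post$counts), 1,
                           channel = "pir")
    w <- select_cycling_window(rec)
    expect_gte(w$start_offset, 9 * 24)
    expect_lte(w$start_offset + w$duration, 21.5 * 24)
    expect_false(attr(w, "low_confidence"))
  }
})

test_that("a purely circadian record is flagged low-confidence", {
  r <- sine_record(24, days = 10, bin_minutes = 1, base = 20, noise_sd = 3,
                   seed = 7, channel = "pir")
  w <- select_cycling_window(r)
  expect_true(attr(w, "low_confidence"))
  expect_lt(attr(w, "ratio"), 1)
})

test_that("daily sleep fractions are recovered and scale-free", {
  for (seed in 1:5) {
    pir <- simulate_pir_sleepwake(sleep_pattern_spec(seed = seed), days = 8)
    sl <- pir_to_sleep(pir)
    lab <- label_days(sl, time_window(0, 8 * 24))
    dsf <- daily_sleep_fraction(sl, lab)
    expect_lt(abs(dsf$mean_fraction[["active"]] - 0.35), 0.02)
    expect_lt(abs(dsf$mean_fraction[["inactive"]] - 0.70), 0.02)
    # fractions depend only on the zero pattern, not count magnitude
    pir10 <- activity_record(pir$counts * 10, 1, channel = "pir")
    dsf10 <- daily_sleep_fraction(pir_to_sleep(pir10), lab)
    expect_identical(dsf10$mean_fraction, dsf$mean_fraction)
  }

  # an all-sleep series saturates at fraction 1 for every label
  allz <- simulate_pir_sleepwake(
    sleep_pattern_spec(active_fraction = 1, inactive_fraction = 1, seed = 1),
    days = 2)
  expect_true(all(allz$counts == 0))
  cyc <- simulate_pir_sleepwake(sleep_pattern_spec(seed = 4), days = 2)
  lab <- label_days(pir_to_sleep(cyc), time_window(0, 48))
  dsf1 <- daily_sleep_fraction(pir_to_sleep(allz), lab)
  expect_true(all(dsf1$per_day$fraction == 1))
})
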