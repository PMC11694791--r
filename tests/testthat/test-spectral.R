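test_that("a pure 48-h tone is recovered far above threshold", {
  r <- sine_record(48, days = 28)
  pg <- lomb_scargle(r)
  pk <- highest_peak(pg)
  expect_true(within_one_grid_step(pk, 48, pg$grid_df))
  expect_gt(max(pg$power), 50 * pg$sig_level)
})

test_that("a constant series yields no significant power", {
  r <- activity_record(rep(7, 3000), 5)
  pg <- suppressWarnings(lomb_scargle(r, c(10, 40)))
  expect_true(all(pg$power == 0))
  expect_false(any(pg$power > pg$sig_level))
})

test_that("LS power equals the brute-force least-squares oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(50:400, 1)
    mask <- runif(n) < 0.2
    r <- activity_record(rpois(n, 10), 30, gap_mask = mask)
    pg <- suppressWarnings(lomb_scargle(r, c(5, 40), oversample = 4))
    t <- time_hours(r)[!mask]
    y <- r$counts[!mask]
    o <- ls_oracle(t, y, pg$periods)
    expect_lt(max(abs(o - pg$power) / pmax(abs(o), 1e-8)), 1e-8)
  }
})

test_that("significance threshold behaves in the alpha limits", {
  # threshold vanishes as alpha approaches 1
  expect_lt(significance_level(100, 1 - 1e-9, 1), 1e-6)
  seq_to_one <- vapply(c(1e-4, 1e-8, 1e-12),
                       function(e) significance_level(100, 1 - e, 100),
                       numeric(1))
  expect_true(all(diff(seq_to_one) < 0))
  a <- seq(0.001, 0.5, length.out = 20)
  th <- vapply(a, function(al) significance_level(100, al, 100), numeric(1))
  expect_true(all(diff(th) < 0))  # threshold strictly increases as alpha halves
  expect_error(significance_level(2, 0.05, 10), "n_effective")
  expect_error(significance_level(100, 1.2, 10), "alpha")
})

test_that("permutation and analytic thresholds agree in order of magnitude", {
  set.seed(5)
  r <- activity_record(rpois(400, 15), 30)
  pga <- suppressWarnings(lomb_scargle(r, c(5, 40), alpha = 0.05))
  pgp <- suppressWarnings(lomb_scargle(r, c(5, 40), alpha = 0.05,
                                       sig_method = "permutation",
                                       n_perm = 100))
  expect_gt(pgp$sig_level, pga$sig_level / 3)
  expect_lt(pgp$sig_level, pga$sig_level * 3)
})

test_that("%ASD puts a lone 48-h peak fully in the infradian band", {
  r <- sine_record(48, days = 28)
  pg <- lomb_scargle(r)
  bp <- percent_asd(pg)
  expect_equal(unname(bp$asd_percent[["20-27h"]]), 0)
  expect_equal(unname(bp$asd_percent[["27-96h"]]), 100)
})

test_that("%ASD bands sum to 100, are scale-invariant, and NA when nothing is significant", {
  # two-tone fixture, direct masked-grid summation oracle
  n <- 28 * 288
  t <- (seq_len(n) - 1) * 5 / 60
  x <- 50 * (2 + sin(2 * pi * t / 24) + sin(2 * pi * t / 48))
  r <- activity_record(round(x), 5)
  pg <- lomb_scargle(r)
  bp <- percent_asd(pg)
  expect_equal(sum(bp$asd_percent), 100, tolerance = 1e-9)
  sig <- pg$power > pg$sig_level
  circ <- sig & pg$periods >= 20 - 1e-9 & pg$periods < 27 - 1e-9
  oracle_circ <- 100 * sum(pg$power[circ]) / sum(pg$power[sig])
  expect_equal(unname(bp$asd_percent[["20-27h"]]), oracle_circ,
               tolerance = 1e-9)

  # uniform count rescaling leaves the partition unchanged
  r10 <- activity_record(round(x) * 10, 5)
  bp10 <- percent_asd(lomb_scargle(r10))
  expect_equal(bp10$asd_percent, bp$asd_percent, tolerance = 1e-9)

  # pure noise at strict alpha: nothing significant -> NA partition
  set.seed(9)
  rn <- activity_record(rpois(2000, 20), 30)
  pgn <- suppressWarnings(lomb_scargle(rn, c(20, 96), alpha = 1e-6))
  bpn <- percent_asd(pgn)
  if (bpn$n_significant == 0) expect_true(all(is.na(bpn$asd_percent)))

  expect_error(percent_asd(pg, c(5, 27, 96)), "outside")
})

test_that("highest_peak obeys amplitude ordering and the null case", {
  n <- 28 * 288
  t <- (seq_len(n) - 1) * 5 / 60
  x <- 50 * (3 + sin(2 * pi * t / 24) + 2 * sin(2 * pi * t / 48))
  pg <- lomb_scargle(activity_record(round(x), 5))
  pk <- highest_peak(pg)
  expect_true(within_one_grid_step(pk, 48, pg$grid_df))

  set.seed(2)
  rn <- activity_record(rpois(2000, 20), 30)
  pgn <- suppressWarnings(lomb_scargle(rn, c(20, 96), alpha = 1e-6))
  if (!any(pgn$power > pgn$sig_level)) expect_true(is.na(highest_peak(pgn)))

  # the peak always falls in a band with positive %ASD
  bp <- percent_asd(pg)
  band <- findInterval(pk, bp$band_edges, rightmost.closed = TRUE)
  expect_gt(bp$asd_percent[[band]], 0)
})

test_that("grid refinement leaves the %ASD partition stable", {
  n <- 28 * 288
  t <- (seq_len(n) - 1) * 5 / 60
  x <- 50 * (2 + sin(2 * pi * t / 24) + sin(2 * pi * t / 48))
  r <- activity_record(round(x), 5)
  b10 <- percent_asd(lomb_scargle(r, oversample = 10))
  b20 <- percent_asd(lomb_scargle(r, oversample = 20))
  expect_lt(max(abs(b10$asd_percent - b20$asd_percent)), 1)
})

test_that("the trough after a lone ultradian peak sits just above it", {
  r <- sine_record(4, days = 4, bin_minutes = 5)
  pg <- lomb_scargle(r, c(2, 24), oversample = 10)
  ts <- trough_after_peak(pg)
  expect_lt(abs(ts$peak_period - 4), 0.1)
  expect_gt(ts$tro, 4)
  expect_lte(ts$tro, 8)
  expect_gt(ts$asd_below_pct, 95)

  # smoothing is a near no-op on a clean single-tone periodogram
  ts_raw <- trough_after_peak(pg, smooth = FALSE)
  expect_equal(ts$tro, ts_raw$tro, tolerance = 0.15)
})
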