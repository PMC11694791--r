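test_that("activity_record validates and masks invalid bins", {
  r <- activity_record(c(1, 2, NA, 4), 5)
  expect_equal(r$gap_mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_true(is.na(r$counts[3]))
  expect_error(activity_record(c(1, -2, 3), 5), "negative")
  expect_error(activity_record(1:4, 5, gap_mask = c(TRUE, FALSE)), "lengths")
  expect_error(activity_record(numeric(0), 5), "empty")
  expect_error(activity_record(1:4, 0), "bin_minutes")
})

test_that("two-column files round-trip and degenerate fields are masked", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,count", paste(seq(0, 55, 5), 1:12, sep = ",")), f)
  r <- load_activity(f)
  expect_equal(length(r$counts), 12L)
  expect_equal(r$bin_minutes, 5)
  expect_false(any(r$gap_mask))
  expect_equal(r$counts, as.numeric(1:12))

  writeLines(c("timestamp,count", "0,4", "5,", "10,7"), f)
  r2 <- load_activity(f)
  expect_equal(r2$gap_mask, c(FALSE, TRUE, FALSE))
  expect_equal(r2$counts[c(1, 3)], c(4, 7))

  writeLines(c("timestamp,count", "0,4", "5,6", "11,7"), f)
  expect_error(load_activity(f), "jitter")
  expect_error(load_activity(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("write/load round trip reproduces numeric content exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(10:60, 1)
    mask <- runif(n) < 0.15
    counts <- rpois(n, 20) + round(runif(n), 3)
    r <- activity_record(counts, sample(c(1, 5, 15), 1), gap_mask = mask)
    write_activity(r, f)
    r2 <- load_activity(f, channel = r$channel)
    expect_identical(r2$counts, r$counts)
    expect_identical(r2$gap_mask, r$gap_mask)
    expect_equal(r2$bin_minutes, r$bin_minutes)
  }
})

test_that("counts dialect reads via YAML sidecar", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(c(3, 0, 5)), f)
  yaml::write_yaml(list(bin_minutes = 1, channel = "pir"), paste0(f, ".yml"))
  r <- load_activity(f)
  expect_equal(r$channel, "pir")
  expect_equal(r$counts, c(3, 0, 5))
  expect_equal(r$bin_minutes, 1)
})

test_that("rebin sums counts, conserves totals, and propagates masks", {
  r <- activity_record(rep(1, 10), 1)
  r5 <- rebin(r, 5)
  expect_equal(r5$counts, c(5, 5))
  expect_equal(r5$bin_minutes, 5)
  expect_identical(rebin(r, 1), r)
  expect_error(rebin(r, 3.5), "multiple")

  # conservation on random gap-free records (brute-force sum oracle)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    rr <- activity_record(rpois(n, 7), 1)
    rb <- rebin(rr, sample(c(2, 5, 10), 1))
    expect_equal(sum(rb$counts), sum(rr$counts))
  }

  # a new bin is masked iff any constituent is masked
  rm <- activity_record(rep(2, 10), 1, gap_mask = c(rep(FALSE, 4), TRUE,
                                                    rep(FALSE, 5)))
  rb <- rebin(rm, 5)
  expect_equal(rb$gap_mask, c(TRUE, FALSE))
  expect_equal(rb$counts[2], 10)
})

test_that("extract_window preserves structure and composes", {
  set.seed(3)
  r <- activity_record(rpois(60 * 288, 5), 5)
  w <- time_window((60 - 14) * 24, 14 * 24)
  sub <- extract_window(r, w)
  expect_equal(span_hours(sub), 14 * 24)
  expect_equal(sub$counts, r$counts[(46 * 288 + 1):(60 * 288)])

  full <- extract_window(r, time_window(0, span_hours(r)))
  expect_equal(full$counts, r$counts)

  # splice: two adjacent windows reproduce the parent
  a <- extract_window(r, time_window(0, 30 * 24))
  b <- extract_window(r, time_window(30 * 24, 30 * 24))
  expect_equal(c(a$counts, b$counts), r$counts)

  # nesting: window-of-window equals one direct extraction
  outer <- extract_window(r, time_window(24, 200))
  inner <- extract_window(outer, time_window(48, 100))
  direct <- extract_window(r, time_window(72, 100))
  expect_equal(inner$counts, direct$counts)

  expect_error(extract_window(r, time_window(59 * 24, 48)), "outside")
})

test_that("masked bins never contribute to downstream statistics", {
  set.seed(11)
  base <- rpois(14 * 288, 20)
  mask <- rep(FALSE, length(base)); mask[sample(length(base), 200)] <- TRUE
  inject <- base; inject[mask] <- 1e9
  r0 <- activity_record(base, 5, gap_mask = mask)
  r1 <- activity_record(inject, 5, gap_mask = mask)
  pg0 <- suppressWarnings(lomb_scargle(r0, c(10, 40)))
  pg1 <- suppressWarnings(lomb_scargle(r1, c(10, 40)))
  expect_identical(pg0$power, pg1$power)
  expect_identical(total_activity(r0), total_activity(r1))
  expect_identical(rebin(r0, 15)$counts, rebin(r1, 15)$counts)
})
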