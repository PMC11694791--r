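test_that("total distance matches closed forms and is an isometry invariant", {
  sq <- path_trace(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0), arena_cm = 50)
  expect_equal(total_distance(sq), 40)

  set.seed(8)
  x <- cumsum(rnorm(500, 0, 0.3)) + 25
  y <- cumsum(rnorm(500, 0, 0.3)) + 25
  tr <- path_trace(x, y)
  # brute-force cumulative-sum oracle
  oracle <- sum(sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(total_distance(tr), oracle, tolerance = 1e-9)

  th <- 0.7
  xr <- 25 + cos(th) * (x - 25) - sin(th) * (y - 25)
  yr <- 25 + sin(th) * (x - 25) + cos(th) * (y - 25)
  expect_equal(total_distance(path_trace(xr, yr)), total_distance(tr),
               tolerance = 1e-9)
})

test_that("microevents fall at 2-cm crossings of cumulative path length", {
  # straight path at 0.5 cm/frame: microevents every 4th frame
  n <- 101
  tr <- path_trace(seq(0, 50, length.out = n), rep(25, n))
  me <- segment_microevents(tr)
  expect_equal(me, seq(1, 101, by = 4))

  # stationary animal: no microevents possible
  still <- path_trace(rep(25, 100), rep(25, 100))
  expect_error(segment_microevents(still), "path length")

  # brute-force crossing oracle on random traces
  for (seed in 1:10) {
    set.seed(seed)
    x <- pmin(pmax(cumsum(rnorm(2000, 0, 0.4)) + 25, 0), 50)
    y <- pmin(pmax(cumsum(rnorm(2000, 0, 0.4)) + 25, 0), 50)
    tr <- path_trace(x, y)
    me <- segment_microevents(tr)
    cl <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    gaps <- diff(cl[me])
    maxstep <- max(sqrt(diff(x)^2 + diff(y)^2))
    expect_true(all(gaps >= 2 - 1e-9 & gaps < 2 + 2 * maxstep))
  }
})

test_that("L_k reproduces the collinear and zigzag hand oracles", {
  line <- cbind(seq(0, 16, by = 2), rep(0, 9))
  for (k in c(1, 2, 4, 8)) {
    expect_equal(path_length_at_resolution(line, k), 16, tolerance = 1e-12)
  }

  zz <- zigzag_corners()
  expect_equal(path_length_at_resolution(zz, 1), 16, tolerance = 1e-9)
  for (k in c(2, 4, 8)) {
    expect_equal(path_length_at_resolution(zz, k), 8 * sqrt(2),
                 tolerance = 1e-9)
  }
  expect_error(path_length_at_resolution(zz[1:5, ], 8), "microevents")

  # metric property: doubling the stride never lengthens the path
  for (seed in 1:10) {
    set.seed(seed)
    pts <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
    for (k in c(1, 2, 4)) {
      expect_lte(path_length_at_resolution(pts, 2 * k),
                 path_length_at_resolution(pts, k) + 1e-12)
    }
  }
})

test_that("spatial d matches the hand OLS oracle and both conventions", {
  # straight path: all L_k equal, slope 0
  n <- 201
  tr <- path_trace(seq(0, 50, length.out = n), seq(0, 50, length.out = n))
  fit <- spatial_d(tr)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$spatial_d, 0, tolerance = 1e-12)
  fit2 <- spatial_d(tr, convention = "one_minus_slope")
  expect_equal(fit2$spatial_d, 1, tolerance = 1e-12)

  # zigzag fixture: OLS on (0,4),(1,log2 8sqrt2),(2,.),(3,.) has slope -0.15
  lk <- c(16, 8 * sqrt(2), 8 * sqrt(2), 8 * sqrt(2))
  slope <- hand_ols_slope(log2(c(1, 2, 4, 8)), log2(lk))
  expect_equal(slope, -0.15, tolerance = 1e-12)

  # rigid-motion invariance of spatial d
  set.seed(12)
  x <- pmin(pmax(cumsum(rnorm(3000, 0, 0.3)) + 25, 0), 50)
  y <- pmin(pmax(cumsum(rnorm(3000, 0, 0.3)) + 25, 0), 50)
  d0 <- spatial_d(path_trace(x, y))$spatial_d
  th <- 1.1
  xr <- cos(th) * (x - 25) - sin(th) * (y - 25) + 25
  yr <- sin(th) * (x - 25) + cos(th) * (y - 25) + 25
  dr <- spatial_d(path_trace(xr, yr, arena_cm = 60))$spatial_d
  expect_equal(dr, d0, tolerance = 1e-9)
})

test_that("straighter generated paths have lower spatial d", {
  lv <- c(0.1, 0.5, 1, 2)
  med <- vapply(lv, function(ts) {
    stats::median(vapply(1:10, function(s) {
      spatial_d(simulate_path(path_spec(turning_sd = ts, seed = s)))$spatial_d
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("ezTrack-style CSVs load with short dropouts bridged", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(frame = 0:99, x = seq(100, 199), y = rep(120, 100))
  d$x[50] <- NA
  utils::write.csv(d, f, row.names = FALSE)
  tr <- load_path_trace(f, calibration = 0.25)
  expect_equal(nrow(tr$xy), 100)
  expect_equal(unname(tr$xy[50, 1]), 0.25 * (148 + 150) / 2, tolerance = 1e-9)
  d$x[10:20] <- NA
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(load_path_trace(f, calibration = 0.25), "consecutive")
})
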