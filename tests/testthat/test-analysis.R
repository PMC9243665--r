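make_trace <- function(cells, grid_dt = 1) {
  structure(list(time = seq(0, by = grid_dt,
                            length.out = ncol(cells)),
                 cells = cells, pop = colMeans(cells),
                 sigma = NA, grid_dt = grid_dt),
            class = "sdf_trace")
}

test_that("SDF of an empty train is zero and of one spike is a Gaussian", {
  tr <- compute_sdf(list(numeric(0)), sigma = 20, t_max = 1000)
  expect_true(all(tr$cells == 0))
  tr <- compute_sdf(list(500), sigma = 20, t_max = 1000)
  # peak 1/(0.020 sqrt(2 pi)) Hz at the spike time, unit integral
  expect_equal(max(tr$cells), 1000 * dnorm(0, sd = 20), tolerance = 1e-6)
  expect_equal(tr$time[which.max(tr$cells)], 500)
  expect_equal(sum(tr$cells) * tr$grid_dt / 1000, 1, tolerance = 0.001)
})

test_that("population SDF of identical cells equals the single-cell SDF", {
  sp <- c(100, 250, 400)
  tr <- compute_sdf(list(sp, sp), sigma = 10, t_max = 1000)
  expect_equal(tr$pop, tr$cells[1, ])
})

test_that("SDF integral equals the spike count within 1%", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    sp <- sort(runif(n, 150, 850))   # away from edges (kernel truncation)
    for (sigma in c(10, 20)) {
      tr <- compute_sdf(list(sp), sigma = sigma, t_max = 1000)
      expect_equal(sum(tr$cells) * tr$grid_dt / 1000, n,
                   tolerance = 0.01)
    }
  }
})

test_that("motor output is a trailing average with edge shrinkage", {
  expect_equal(motor_output(rep(7, 500), 100), rep(7, 500))
  x <- numeric(500); x[200] <- 1
  mo <- motor_output(x, 100)
  expect_equal(mo[250], 1 / 100)            # plateau height dt / window
  expect_equal(mo[350], 0)                  # impulse has left the window
  expect_lte(max(mo), max(x))
  set.seed(1)
  y <- runif(400, 0, 10)
  expect_lte(max(motor_output(y, 100)), max(y))
  expect_gte(min(motor_output(y, 100)), min(y))
})

test_that("a flat zero trace is never a conditioned response", {
  det <- detect_cr(numeric(1000), analysis_config())
  expect_false(det$cr)
  expect_true(is.na(det$onset))
})

test_that("a ramp crossing threshold gives the hand-traced onset", {
  # ramp from 0 at 120 ms to 8 Hz at 280 ms; threshold 4 Hz; US at 250 ms
  t <- 0:999
  trace <- pmax(0, (t - 120) * 8 / 160)
  det <- detect_cr(trace, analysis_config(), us_onset = 250)
  expect_true(det$cr)
  expect_equal(det$onset, 130, tolerance = 2)   # rise starts at 120 ms
})

test_that("responses confined to the first 100 ms do not count", {
  t <- 0:999
  bump <- 8 * exp(-((t - 50) / 15)^2)           # early bump, gone by 100 ms
  det <- detect_cr(bump, analysis_config(), us_onset = 250)
  expect_false(det$cr)
})

test_that("raising the threshold never converts a non-CR into a CR", {
  set.seed(7)
  for (rep in 1:20) {
    trace <- pmax(0, cumsum(rnorm(1000, 0.002, 0.2)))
    flags <- vapply(seq(0.5, 10, by = 0.5), function(th)
      detect_cr(trace, analysis_config(), threshold = th)$cr, TRUE)
    # the CR indicator must be non-increasing along increasing thresholds
    expect_true(all(diff(as.integer(flags)) <= 0))
  }
})

test_that("SDF change is zero for stationary activity", {
  cells <- matrix(10, nrow = 3, ncol = 1000)
  expect_equal(sdf_change(list(make_trace(cells))), rep(0, 3))
})

test_that("SDF change matches piecewise-constant arithmetic", {
  # 10 Hz in the first 100 ms, 4 Hz in the CR window of 180 ms
  cells <- matrix(0, 1, 1000)
  cells[1, 1:100] <- 10
  cells[1, 101:280] <- 4
  ch <- sdf_change(list(make_trace(cells)))
  expect_equal(ch, 4 * 0.18 - 10 * 0.18, tolerance = 1e-12)
  expect_lt(ch, 0)   # suppression is negative by convention
})

test_that("baseline statistics match hand arithmetic", {
  # regular 10 Hz in the baseline window
  sp <- seq(300, 990, by = 100)
  st <- baseline_stats(list(sp))
  expect_equal(st$rate, length(sp) / 0.72)
  expect_equal(st$cv_isi, 0)
  # ISIs 10 and 30 ms: mean 20, sample sd 14.14, CV 0.707
  st <- baseline_stats(list(c(500, 510, 540)))
  expect_equal(st$cv_isi, sqrt(200) / 20, tolerance = 1e-12)
  # long Poisson train: CV near 1
  set.seed(3)
  sp <- cumsum(rexp(20000, rate = 30 / 1000))
  st <- baseline_stats(list(sp[sp >= 280 & sp <= 1000]),
                       window = c(280, 1000))
  isi_cv <- st$cv_isi
  set.seed(3)
  long <- baseline_stats(list(cumsum(rexp(5000, 1 / 20))),
                         window = c(0, 100000))
  expect_equal(long$cv_isi, 1, tolerance = 0.1)
  # fewer than three spikes: undefined CV
  expect_true(is.na(baseline_stats(list(c(400, 600)))$cv_isi))
})

test_that("Tukey fences exclude the obvious outlier and keep ties", {
  expect_equal(exclude_outliers(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(exclude_outliers(rep(5, 6)), rep(5, 6))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(exclude_outliers(x), x)       # order preserved, none outside
  expect_error(exclude_outliers(c(1, 2, 3)), "at least 4")
})

test_that("threshold calibration places block six at the target rate", {
  set.seed(9)
  strengths <- c(rnorm(50, 2, 0.3), rnorm(50, 8, 2))   # learning-like
  thr <- calibrate_cr_threshold(strengths, block = 6, block_size = 10,
                                target = 0.7)
  blk <- strengths[51:60]
  expect_equal(sum(blk >= thr), 7)
  # degenerate block: falls back to the configured default
  expect_equal(calibrate_cr_threshold(rep(0, 100), fallback = 4), 4)
})
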