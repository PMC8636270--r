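make_series <- function(u, v, w, c, fs) {
  n <- length(w)
  flux_series((seq_len(n) - 1) / fs, rep_len(u, n), rep_len(v, n),
              w, c, fs = fs)
}

test_that("downsampling block-averages velocity onto the scalar rate", {
  n <- 64
  s <- make_series(u = 1:n, v = 0, w = rep(c(1, -1), n / 2), c = 1:n, fs = 16)
  s$u <- as.numeric(1:n)
  d <- downsample(s, 4)
  expect_equal(nrow(d), n / 4)
  expect_equal(d$u, colMeans(matrix(1:n, nrow = 4)))
  # alternating +/-1 at 16 Hz averages to exactly zero at 4 Hz
  expect_equal(d$w, rep(0, n / 4))
  # constant channels are unchanged
  s2 <- make_series(u = 0.3, v = 0, w = rep(2, n), c = rep(5, n), fs = 16)
  expect_equal(downsample(s2, 4)$w, rep(2, n / 4))
  expect_error(downsample(s, 32), "above the source rate")
})

test_that("despiking flags and replaces isolated outliers, and only those", {
  set.seed(1)
  n <- 10000
  w <- rnorm(n)
  w[5000] <- w[5000] + 10 * mad(w)   # injected spike
  s <- make_series(0.1, 0, w, rnorm(n), fs = 4)
  out <- despike(s, k_mad = 6, window = 9)
  rep <- attr(out, "spike_report")
  expect_true(5000 %in% rep$indices$w)
  expect_false(out$w[5000] == w[5000])
  # spike-free Gaussian noise at k_mad = 6: < 0.1% flagged
  s2 <- make_series(0.1, 0, rnorm(n), rnorm(n), fs = 4)
  out2 <- despike(s2, k_mad = 6, window = 9)
  expect_lt(attr(out2, "spike_report")$count / n, 0.001)
  # all-constant series is a no-op with zero spikes
  s3 <- make_series(0.1, 0, rep(0, 100), rep(1, 100), fs = 4)
  out3 <- despike(s3)
  expect_identical(out3$w, rep(0, 100))
  expect_equal(attr(out3, "spike_report")$count, 0L)
  expect_error(despike(s, window = 4), "odd")
})

test_that("double rotation zeroes mean v and w and preserves speed", {
  set.seed(2)
  n <- 2000
  s <- make_series(0.05, 0, 0.02 + rnorm(n, 0, 0.005), rnorm(n), fs = 4)
  s$u <- 0.05 + rnorm(n, 0, 0.005)
  s$v <- 0.01 + rnorm(n, 0, 0.005)
  r <- rotate_tilt(s)
  speed <- sqrt(s$u^2 + s$v^2 + s$w^2)
  expect_lt(abs(mean(r$v)), 1e-10 * mean(speed))
  expect_lt(abs(mean(r$w)), 1e-10 * mean(speed))
  expect_equal(sqrt(r$u^2 + r$v^2 + r$w^2), speed, tolerance = 1e-12)
  # an already aligned series is (nearly) untouched
  s2 <- make_series(0.05, 0, rnorm(n, 0, 0.005), rnorm(n), fs = 4)
  s2$w <- s2$w - mean(s2$w)
  r2 <- rotate_tilt(s2)
  expect_equal(r2$u, s2$u, tolerance = 1e-6)
})

test_that("rotation matches a hand-applied rotation on a 3-sample toy", {
  # pure w-offset: the offset must move into u, covariances preserved
  s <- make_series(1, 0, c(0.1, 0.1, 0.1), c(1, 2, 3), fs = 1)
  s$u <- c(1, 1, 1)
  r <- rotate_tilt(s)
  beta <- atan2(0.1, 1)
  expect_equal(r$u, c(1, 1, 1) * cos(beta) + 0.1 * sin(beta), tolerance = 1e-12)
  expect_equal(r$w, rep(0, 3), tolerance = 1e-12)
  expect_equal(var(r$u) + var(r$w), var(s$u) + var(s$w), tolerance = 1e-12)
  s0 <- make_series(0, 0, rep(0, 10), rep(0, 10), fs = 1)
  expect_error(rotate_tilt(s0), "zero")
})

test_that("decomposition conserves the signal and splits frequencies", {
  fs <- 4
  t <- (0:(4 * 3600 - 1)) / fs
  w <- 0.01 * sin(2 * pi * t / 20)
  s <- make_series(0.05, 0, w, 250 + 3 * sin(2 * pi * t / 20), fs = fs)
  d <- decompose(s, cutoff_s = 300)
  # conservation: steady + fluctuating = input
  expect_lt(max(abs(d$steady$c + d$fluctuating$c - s$c)), 1e-9 * max(abs(s$c)))
  # a sinusoid much faster than the cutoff lands in the fluctuating part
  mid <- seq(2000, length(t) - 2000)
  expect_gt(sd(d$fluctuating$w[mid]) / sd(w[mid]), 0.99)
  # a constant series has zero fluctuation
  s2 <- make_series(0.05, 0, rep(1, 4000), rep(250, 4000), fs = fs)
  d2 <- decompose(s2, cutoff_s = 300)
  expect_equal(d2$fluctuating$c, rep(0, 4000))
  expect_error(decompose(s, cutoff_s = 0.2), "two samples")
})

test_that("lag optimization recovers injected shifts and breaks ties to 0", {
  fs <- 4
  t <- (0:20000) / fs
  w <- sin(2 * pi * t / 30) + 0.3 * sin(2 * pi * t / 17)
  for (lag in c(0, 1.25, 2.5, -2)) {
    c_sig <- sin(2 * pi * (t - lag) / 30) + 0.3 * sin(2 * pi * (t - lag) / 17)
    expect_equal(optimize_lag(w, c_sig, max_lag_s = 10, fs = fs), lag)
  }
  # anti-correlated input: the maximum of the signed correlation wins,
  # checked against a brute-force scan
  c_anti <- -w
  brute <- sapply(-40:40, function(k) {
    al <- align_lag(w, c_anti, k)
    cor(al$w, al$c)
  })
  got <- optimize_lag(w, c_anti, 10, fs)
  al <- align_lag(w, c_anti, round(got * fs))
  expect_equal(cor(al$w, al$c), max(brute), tolerance = 1e-12)
  # maximizing |correlation| would pick lag 0 (cor = -1); the signed
  # convention must not
  expect_false(got == 0)
  expect_gt(abs(brute[41]), max(brute))
  expect_error(optimize_lag(rep(0, 100), rnorm(100), 5, fs), "zero-variance")
})

test_that("instantaneous flux follows the sinusoid closed forms", {
  fs <- 8
  t <- (0:(fs * 600 - 1)) / fs    # integer number of 20-s periods
  A <- 0.02; B <- 1
  w <- A * sin(2 * pi * t / 20)
  c_in <- B * sin(2 * pi * t / 20)
  expect_equal(mean(instantaneous_flux(w, c_in)), A * B / 2, tolerance = 1e-9)
  # orthogonal sin/cos average to zero flux
  expect_equal(mean(instantaneous_flux(w, B * cos(2 * pi * t / 20))), 0,
               tolerance = 1e-12)
  expect_equal(mean(instantaneous_flux(w, c_in)), 0.01, tolerance = 1e-9)
  expect_error(instantaneous_flux(w, c_in[-1]), "mismatch")
})

test_that("cumulative flux integrates and truncates on jumps", {
  fs <- 4
  f <- rep(0.01, 1000)
  cum <- cumulative_flux(f, 1 / fs)
  expect_equal(cum[length(cum)], 0.01 * 999 / fs, tolerance = 1e-12)
  # an injected step 100x the typical increment truncates exactly there
  f2 <- rnorm(1000, 0.01, 0.001)
  f2[600] <- f2[600] + 100 * 0.01 * fs
  cum2 <- cumulative_flux(f2, 1 / fs)
  tr <- truncate_on_jump(cum2, jump_k = 50)
  expect_true(tr$jump_detected)
  expect_equal(tr$index, 599)
  expect_false(truncate_on_jump(cum2, jump_k = Inf)$jump_detected)
})

test_that("burst averaging converts units and flags incomplete bursts", {
  fs <- 4
  b <- burst_average(rep(0.01, 2 * 3600 * fs), fs)
  expect_equal(nrow(b), 2)
  expect_equal(b$flux, c(36, 36))
  expect_false(any(b$truncated))
  b2 <- burst_average(rep(0, 3600 * fs + 100), fs)
  expect_equal(b2$flux, c(0, 0))
  expect_true(b2$truncated[2])
  expect_error(burst_average(numeric(0), fs), "empty")
})

test_that("daily summary integrates day and night and propagates s.d.", {
  fl <- c(rep(2, 12), rep(-1, 12)) / 3600   # mmol m-2 s-1 burst means
  b <- burst_average(rep(fl, each = 3600), fs = 1)
  par <- c(rep(100, 12), rep(0, 12))
  d <- daily_flux(b, par)
  expect_equal(d$net_daily, (2 * 12 - 1 * 12))
  expect_equal(d$day_mean, 2)
  expect_equal(d$night_mean, -1)
  expect_equal(d$co2_daily, -d$net_daily)
  # quadrature sum of day and night s.d.
  fl2 <- c(1, 3, rep(2, 10), -2, 0, rep(-1, 10)) / 3600
  b2 <- burst_average(rep(fl2, each = 3600), fs = 1)
  d2 <- daily_flux(b2, par)
  expect_equal(d2$sd_propagated,
               sqrt(sd(fl2[1:12] * 3600)^2 + sd(fl2[13:24] * 3600)^2))
  # all-zero bursts, all day: zero flux, zero sd, partial result flagged
  b3 <- burst_average(rep(0, 2 * 3600), fs = 1)
  d3 <- daily_flux(b3, c(10, 10))
  expect_equal(d3$net_daily, 0)
  expect_equal(d3$sd_propagated, 0)
  expect_true(d3$partial)
})

test_that("the full chain recovers a synthetic flux within 5%", {
  rec <- gen_ec_timeseries(ec_truth(true_flux = 1.5, lag_s = 2.5, tilt_deg = 5,
                                    spike_count = 5, seed = 21),
                           duration_s = 21600, snr = 5)
  res <- ec_process(rec)
  expect_equal(res$lag_s, 2.5)
  hourly <- mean(res$bursts$flux[!res$bursts$truncated])
  expect_lt(abs(hourly - 1.5) / 1.5, 0.05)
})
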