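#' Synchronized eddy-covariance time series
#'
#' A `flux_series` is a data frame with one row per sample at a single,
#' common sampling rate: `time` (s, strictly increasing), velocity
#' components `u`, `v`, `w` (m s^-1), the scalar `c` (O2 concentration,
#' mmol m^-3), and optional `par` and `temp` channels. The sampling rate is
#' carried in the `fs` attribute.
#'
#' @param time sample times in seconds, strictly increasing and equispaced.
#' @param u,v,w velocity components (m s^-1).
#' @param c scalar concentration (mmol m^-3).
#' @param par optional photosynthetically active radiation (arbitrary units).
#' @param temp optional temperature (degrees C).
#' @param fs sampling rate in Hz; inferred from `time` when omitted.
#' @return A data frame of class `flux_series`.
#' @export
flux_series <- function(time, u, v, w, c, par = NULL, temp = NULL, fs = NULL) {
  n <- length(time)
  if (n < 2L) stop("a flux_series needs at least two samples")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  lens <- c(length(u), length(v), length(w), length(c))
  if (any(lens != n)) stop("all channels must have the same length as time")
  df <- data.frame(time = time, u = u, v = v, w = w, c = c)
  if (!is.null(par)) {
    stopifnot(length(par) == n)
    df$par <- par
  }
  if (!is.null(temp)) {
    stopifnot(length(temp) == n)
    df$temp <- temp
  }
  df$qc_flags <- integer(n)
  if (is.null(fs)) fs <- 1 / stats::median(diff(time))
  structure(df, fs = fs, class = c("flux_series", "data.frame"))
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series> %d samples at %.3g Hz (%.2f h)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs") / 3600))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

fs_of <- function(series) {
  fs <- attr(series, "fs")
  if (is.null(fs)) stop("series has no sampling-rate attribute 'fs'")
  fs
}

#' Block-average velocity channels onto the scalar sampling rate
#'
#' Velocity is recorded faster (e.g. 16 Hz) than the oxygen optode
#' (1-4 Hz); processing starts by downsampling the current data to the
#' frequency of the O2 measurements. Each output sample is the mean of the
#' `fs_vel / target_hz` velocity samples covering one scalar interval.
#'
#' For an `ec_recording` (separate velocity and scalar tables as produced by
#' [gen_ec_timeseries()]) this also synchronizes the two tables into one
#' `flux_series`. For an already-synchronized `flux_series` all channels are
#' block-averaged.
#'
#' @param series an `ec_recording` or `flux_series`.
#' @param target_hz target sampling rate; must divide the source rate.
#' @return A `flux_series` at `target_hz`.
#' @export
downsample <- function(series, target_hz) {
  UseMethod("downsample")
}

block_means <- function(x, k) {
  n_out <- floor(length(x) / k)
  colMeans(matrix(x[seq_len(n_out * k)], nrow = k))
}

#' @export
downsample.ec_recording <- function(series, target_hz = series$fs_o2) {
  if (target_hz <= 0) stop("target_hz must be positive")
  if (target_hz > series$fs_vel) stop("cannot downsample to a rate above the source rate")
  k <- series$fs_vel / target_hz
  if (abs(k - round(k)) > 1e-8) stop("target_hz must divide the velocity rate")
  k <- as.integer(round(k))
  vel <- series$velocity
  u <- block_means(vel$u, k); v <- block_means(vel$v, k); w <- block_means(vel$w, k)
  sc <- series$scalar
  ks <- series$fs_o2 / target_hz
  if (abs(ks - round(ks)) > 1e-8) stop("target_hz must divide the scalar rate")
  ks <- as.integer(round(ks))
  c_out <- block_means(sc$c, ks)
  par_out <- if (!is.null(sc$par)) block_means(sc$par, ks)
  temp_out <- if (!is.null(sc$temp)) block_means(sc$temp, ks)
  n <- min(length(u), length(c_out))
  time <- (seq_len(n) - 1) / target_hz
  flux_series(time, u[seq_len(n)], v[seq_len(n)], w[seq_len(n)], c_out[seq_len(n)],
              par = if (!is.null(par_out)) par_out[seq_len(n)],
              temp = if (!is.null(temp_out)) temp_out[seq_len(n)],
              fs = target_hz)
}

#' @export
downsample.flux_series <- function(series, target_hz) {
  fs <- fs_of(series)
  if (target_hz <= 0) stop("target_hz must be positive")
  if (target_hz > fs) stop("cannot downsample to a rate above the source rate")
  k <- fs / target_hz
  if (abs(k - round(k)) > 1e-8) stop("target_hz must divide the source rate")
  k <- as.integer(round(k))
  cols <- setdiff(names(series), c("time", "qc_flags"))
  out <- lapply(series[cols], block_means, k = k)
  n <- length(out[[1]])
  flux_series((seq_len(n) - 1) / target_hz, out$u, out$v, out$w, out$c,
              par = out$par, temp = out$temp, fs = target_hz)
}

#' Replace spikes by the running median
#'
#' Samples deviating from the running median by more than `k_mad` times the
#' MAD of the residuals are flagged and replaced by the running median.
#' A constant channel has zero MAD and is returned untouched.
#'
#' @param series a `flux_series`.
#' @param k_mad threshold in MAD units (default 6).
#' @param window odd running-median window length in samples (default 9).
#' @param cols channels to despike (default the velocity components, the
#'   channels despiked before tilt correction).
#' @return The despiked `flux_series`; attribute `spike_report` holds, per
#'   channel, the flagged indices and the total count, and flagged samples
#'   are marked in `qc_flags`.
#' @export
despike <- function(series, k_mad = 6, window = 9, cols = c("u", "v", "w")) {
  stopifnot(inherits(series, "flux_series"))
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  report <- list()
  for (col in cols) {
    x <- series[[col]]
    med <- stats::runmed(x, window, endrule = "median")
    resid <- x - med
    s <- stats::mad(resid)
    idx <- if (s > 0) which(abs(resid) > k_mad * s) else integer(0)
    if (length(idx)) {
      x[idx] <- med[idx]
      series[[col]] <- x
      series$qc_flags[idx] <- bitwOr(series$qc_flags[idx], 1L)
    }
    report[[col]] <- idx
  }
  attr(series, "spike_report") <- list(indices = report,
                                       count = sum(lengths(report)))
  series
}

#' Correct instrument tilt by double rotation
#'
#' Standard double rotation of the velocity vector: a first rotation about
#' the vertical axis zeroes the mean transverse velocity (`mean(v) = 0`), a
#' second rotation about the new transverse axis zeroes the mean vertical
#' velocity (`mean(w) = 0`). This aligns the x axis with the mean current
#' and removes the tilt of the velocimeter. The rotation is rigid, so
#' per-sample speed is preserved.
#'
#' @param series a `flux_series` with non-zero mean horizontal speed.
#' @return The rotated `flux_series`; attribute `rotation` records the yaw
#'   and pitch angles (radians).
#' @export
rotate_tilt <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  mu <- mean(series$u); mv <- mean(series$v); mw <- mean(series$w)
  if (sqrt(mu^2 + mv^2 + mw^2) < 1e-12) {
    stop("mean velocity vector is zero: tilt rotation undefined")
  }
  yaw <- atan2(mv, mu)
  u1 <- series$u * cos(yaw) + series$v * sin(yaw)
  v1 <- -series$u * sin(yaw) + series$v * cos(yaw)
  pitch <- atan2(mw, mean(u1))
  u2 <- u1 * cos(pitch) + series$w * sin(pitch)
  w2 <- -u1 * sin(pitch) + series$w * cos(pitch)
  series$u <- u2; series$v <- v1; series$w <- w2
  attr(series, "rotation") <- list(yaw = yaw, pitch = pitch)
  series
}

running_mean <- function(x, halfwidth) {
  n <- length(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - halfwidth, 1L)
  hi <- pmin(i + halfwidth, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Decompose channels into steady and fluctuating components
#'
#' A centered moving-average low-pass filter (window `cutoff_s`, shrinking
#' symmetrically at the edges) defines the steady component; the fluctuating
#' component is the residual, so `steady + fluctuating` reproduces the input
#' exactly.
#'
#' @param series a `flux_series`.
#' @param cutoff_s averaging window in seconds (default 300); must span more
#'   than two samples.
#' @param cols channels to decompose.
#' @return A list with `steady` and `fluctuating` data frames (same columns).
#' @export
decompose <- function(series, cutoff_s = 300, cols = c("u", "v", "w", "c")) {
  stopifnot(inherits(series, "flux_series"))
  fs <- fs_of(series)
  if (cutoff_s <= 2 / fs) stop("cutoff_s must span more than two samples")
  h <- floor(cutoff_s * fs / 2)
  steady <- as.data.frame(lapply(series[cols], running_mean, halfwidth = h))
  fluct <- as.data.frame(mapply(function(x, s) x - s,
                                series[cols], steady, SIMPLIFY = FALSE))
  list(steady = steady, fluctuating = fluct)
}

#' Find the scalar-sensor lag by maximizing cross-correlation
#'
#' The fluctuating scalar series is shifted against the vertical velocity
#' fluctuations until their correlation is maximal (for benthic O2
#' measurements the lag is typically 2-3 s, set by the sensor offset and low
#' horizontal velocities). Positive lag means the scalar is delayed relative
#' to `w`. Ties are broken toward the smallest absolute lag, and it is the
#' signed correlation that is maximized (not its magnitude), so
#' anti-correlated signals select the shift where the correlation is least
#' negative.
#'
#' @param w_fluct fluctuating vertical velocity.
#' @param c_fluct fluctuating scalar, same length and rate.
#' @param max_lag_s search bound in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @return Lag in seconds (a multiple of `1/fs`).
#' @export
optimize_lag <- function(w_fluct, c_fluct, max_lag_s = 10, fs) {
  if (length(w_fluct) != length(c_fluct)) stop("inputs must have equal length")
  if (max_lag_s <= 0) stop("max_lag_s must be positive")
  if (stats::sd(w_fluct) == 0 || stats::sd(c_fluct) == 0) {
    stop("zero-variance input: lag undefined")
  }
  kmax <- floor(max_lag_s * fs)
  ks <- 0:kmax
  cand <- unique(as.vector(rbind(ks, -ks)))   # 0, 1, -1, 2, -2, ... smallest |k| first
  best_k <- 0L; best_cor <- -Inf
  for (k in cand) {
    al <- align_lag(w_fluct, c_fluct, k)
    r <- suppressWarnings(stats::cor(al$w, al$c))
    if (is.finite(r) && r > best_cor + 1e-12) {
      best_cor <- r
      best_k <- k
    }
  }
  best_k / fs
}

#' Align scalar and vertical-velocity series for a given lag
#'
#' Shifts the scalar forward by `lag_samples` (positive lag = scalar delayed
#' relative to `w`) and trims both series to the overlapping part.
#'
#' @param w,c fluctuating series of equal length.
#' @param lag_samples signed integer lag in samples.
#' @return List with aligned `w` and `c`.
#' @export
align_lag <- function(w, c, lag_samples) {
  n <- length(w)
  k <- as.integer(lag_samples)
  if (abs(k) >= n) stop("lag exceeds series length")
  if (k >= 0) {
    list(w = w[seq_len(n - k)], c = c[seq.int(1 + k, n)])
  } else {
    list(w = w[seq.int(1 - k, n)], c = c[seq_len(n + k)])
  }
}

#' Instantaneous turbulent flux
#'
#' Elementwise product of the vertical velocity fluctuations and the
#' lag-aligned scalar fluctuations, `w' * C'`, in mmol m^-2 s^-1
#' (m s^-1 times mmol m^-3).
#'
#' @param w_fluct fluctuating vertical velocity (m s^-1).
#' @param c_fluct_shifted lag-aligned fluctuating scalar (mmol m^-3).
#' @return Flux series in mmol m^-2 s^-1.
#' @export
instantaneous_flux <- function(w_fluct, c_fluct_shifted) {
  if (length(w_fluct) != length(c_fluct_shifted)) {
    stop("length mismatch between w' and C'")
  }
  w_fluct * c_fluct_shifted
}

#' Cumulative (time-integrated) flux
#'
#' Trapezoidal integration of the instantaneous flux; used to screen for
#' sudden jumps that indicate erroneous measurements.
#'
#' @param flux instantaneous flux (mmol m^-2 s^-1).
#' @param dt sample interval in seconds.
#' @return Cumulative flux (mmol m^-2), same length as `flux`, starting at 0.
#' @export
cumulative_flux <- function(flux, dt) {
  if (!all(is.finite(flux))) stop("flux series must be finite")
  n <- length(flux)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((flux[-1] + flux[-n]) / 2 * dt))
}

#' Truncate a cumulative-flux series at the first sudden jump
#'
#' An increment whose magnitude exceeds `jump_k` times the MAD of all
#' increments is treated as an erroneous jump; the series is truncated just
#' before the first such increment. `jump_k = Inf` disables truncation.
#'
#' @param cumulative cumulative flux series.
#' @param jump_k threshold in MAD units (default 50).
#' @return List with `series` (possibly truncated), `index` (first retained
#'   length, `NA` if no truncation) and `jump_detected`.
#' @export
truncate_on_jump <- function(cumulative, jump_k = 50) {
  inc <- diff(cumulative)
  s <- stats::mad(inc)
  if (!is.finite(jump_k) || s == 0 || length(inc) == 0) {
    return(list(series = cumulative, index = NA_integer_, jump_detected = FALSE))
  }
  bad <- which(abs(inc) > jump_k * s)
  if (!length(bad)) {
    return(list(series = cumulative, index = NA_integer_, jump_detected = FALSE))
  }
  cut <- bad[1]
  list(series = cumulative[seq_len(cut)], index = cut, jump_detected = TRUE)
}

#' Average instantaneous fluxes into bursts
#'
#' Means over consecutive bursts (default 60 min), converted from
#' mmol m^-2 s^-1 to mmol m^-2 h^-1. An incomplete trailing burst is kept
#' but flagged `truncated`.
#'
#' @param flux instantaneous flux series (mmol m^-2 s^-1).
#' @param fs sampling rate in Hz.
#' @param burst_s burst length in seconds (default 3600).
#' @param t0 time of the first sample (s), used only for interval labels.
#' @return A data frame of class `burst_flux` with columns `t_start`,
#'   `t_end`, `flux` (mmol m^-2 h^-1), `n_samples`, `truncated`.
#' @export
burst_average <- function(flux, fs, burst_s = 3600, t0 = 0) {
  n <- length(flux)
  if (n == 0) stop("empty flux series")
  per <- as.integer(round(burst_s * fs))
  if (per < 1) stop("burst shorter than one sample")
  grp <- (seq_len(n) - 1L) %/% per
  means <- tapply(flux, grp, mean)
  counts <- tapply(flux, grp, length)
  k <- length(means)
  out <- data.frame(
    t_start = t0 + (seq_len(k) - 1) * burst_s,
    t_end = t0 + (seq_len(k) - 1) * burst_s + as.vector(counts) / fs,
    flux = as.vector(means) * 3600,
    n_samples = as.integer(counts),
    truncated = as.vector(counts) < per
  )
  class(out) <- c("burst_flux", "data.frame")
  out
}

#' Daily net flux from hourly bursts
#'
#' Bursts are classified as day or night by their mean PAR against a
#' threshold (default 1% of the maximum burst PAR). The daily net flux is
#' the mean of the hourly burst fluxes times 24; its uncertainty is the
#' quadrature sum of the day and night standard deviations (the convention
#' used for the error bars on daily fluxes). Negative night fluxes represent
#' respiration; the CO2-equivalent flux is the O2 flux times -1, using a
#' 1 mol O2 : 1 mol CO2 ratio.
#'
#' @param bursts a `burst_flux` data frame.
#' @param par_burst mean PAR per burst (same length as `bursts`).
#' @param par_threshold PAR value above which a burst counts as day;
#'   default 1% of `max(par_burst)`.
#' @param use_truncated include bursts flagged `truncated` (default: only
#'   bursts with at least half the nominal samples).
#' @return List of class `daily_flux` with `net_daily` and `co2_daily`
#'   (mmol m^-2 d^-1), `sd_propagated`, `day_mean`, `night_mean`
#'   (mmol m^-2 h^-1), `n_day`, `n_night`, and `partial` (TRUE when one of
#'   the classes is empty).
#' @export
daily_flux <- function(bursts, par_burst, par_threshold = NULL,
                       use_truncated = NULL) {
  stopifnot(inherits(bursts, "burst_flux"))
  if (length(par_burst) != nrow(bursts)) {
    stop("par_burst must have one value per burst")
  }
  keep <- if (is.null(use_truncated)) {
    bursts$n_samples >= 0.5 * max(bursts$n_samples)
  } else if (use_truncated) rep(TRUE, nrow(bursts)) else !bursts$truncated
  b <- bursts[keep, ]; p <- par_burst[keep]
  if (is.null(par_threshold)) par_threshold <- 0.01 * max(p)
  day <- p > par_threshold
  n_day <- sum(day); n_night <- sum(!day)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  day_mean <- if (n_day) mean(b$flux[day]) else NA_real_
  night_mean <- if (n_night) mean(b$flux[!day]) else NA_real_
  res <- list(
    net_daily = mean(b$flux) * 24,
    co2_daily = -mean(b$flux) * 24,
    sd_propagated = sqrt(sd0(b$flux[day])^2 + sd0(b$flux[!day])^2),
    day_mean = day_mean, night_mean = night_mean,
    n_day = n_day, n_night = n_night,
    partial = n_day == 0 || n_night == 0
  )
  class(res) <- "daily_flux"
  res
}

#' @export
print.daily_flux <- function(x, ...) {
  cat(sprintf("<daily_flux> net O2 %.2f (CO2 %.2f) mmol m-2 d-1, sd %.2f\n",
              x$net_daily, x$co2_daily, x$sd_propagated))
  cat(sprintf("  day %.2f (n=%d), night %.2f (n=%d) mmol m-2 h-1%s\n",
              x$day_mean, x$n_day, x$night_mean, x$n_night,
              if (x$partial) " [partial: one class empty]" else ""))
  invisible(x)
}

#' Full eddy-covariance processing chain
#'
#' Runs the standard benthic processing sequence on a raw recording:
#' downsample the velocity to the scalar rate, despike, double-rotation tilt
#' correction, low-pass decomposition into steady and fluctuating parts, lag
#' optimization of the scalar against `w'`, instantaneous fluxes, cumulative
#' -flux jump screening, 60-min burst averages and the daily summary.
#'
#' @param rec an `ec_recording` from [gen_ec_timeseries()] or a
#'   synchronized `flux_series` with a `par` channel.
#' @param cutoff_s low-pass window (s), default 300.
#' @param k_mad,window despiking parameters, see [despike()].
#' @param max_lag_s lag search bound (s), default 10.
#' @param jump_k cumulative-jump threshold in MAD units, default 50.
#' @param burst_s burst length (s), default 3600.
#' @param par_threshold PAR day/night threshold; default 1% of maximum.
#' @return List with `bursts`, `daily`, `lag_s`, `spike_count`,
#'   `truncation`, and the processed `series`.
#' @export
ec_process <- function(rec, cutoff_s = 300, k_mad = 6, window = 9,
                       max_lag_s = 10, jump_k = 50, burst_s = 3600,
                       par_threshold = NULL) {
  series <- if (inherits(rec, "flux_series")) rec else downsample(rec)
  fs <- fs_of(series)
  series <- despike(series, k_mad = k_mad, window = window)
  spike_count <- attr(series, "spike_report")$count
  series <- rotate_tilt(series)
  dec <- decompose(series, cutoff_s = cutoff_s)
  lag_s <- optimize_lag(dec$fluctuating$w, dec$fluctuating$c, max_lag_s, fs)
  al <- align_lag(dec$fluctuating$w, dec$fluctuating$c, round(lag_s * fs))
  flux <- instantaneous_flux(al$w, al$c)
  cum <- cumulative_flux(flux, 1 / fs)
  tr <- truncate_on_jump(cum, jump_k)
  if (tr$jump_detected) flux <- flux[seq_len(tr$index)]
  bursts <- burst_average(flux, fs, burst_s = burst_s)
  par <- series$par
  if (is.null(par)) stop("recording has no PAR channel; daily summary needs day/night classification")
  par <- par[seq_along(flux)]
  grp <- (seq_along(par) - 1L) %/% as.integer(round(burst_s * fs))
  par_burst <- as.vector(tapply(par, grp, mean))
  daily <- daily_flux(bursts, par_burst, par_threshold = par_threshold)
  list(bursts = bursts, daily = daily, lag_s = lag_s,
       spike_count = spike_count, truncation = tr, series = series)
}
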