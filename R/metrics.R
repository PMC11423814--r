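## Oscillation metrics: period/amplitude extraction, measurement noise,
## zero-phase low-pass filtering and the circadian power fraction.

## local maxima with quadratic sub-grid refinement; returns times and values
find_peaks <- function(t, x) {
  n <- length(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) return(data.frame(t = numeric(0), x = numeric(0)))
  tt <- t[idx]; xx <- x[idx]
  for (j in seq_along(idx)) {
    i <- idx[j]
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      d <- 0.5 * (y1 - y3) / den
      d <- max(-0.5, min(0.5, d))
      tt[j] <- t[i] + d * (t[i + 1] - t[i])
      xx[j] <- y2 - 0.25 * (y1 - y3) * d
    }
  }
  data.frame(t = tt, x = xx)
}

#' Oscillation period and amplitude of a trajectory
#'
#' Period is the mean peak-to-peak interval after discarding the first peak
#' (which carries the initial transient). Amplitude is the mean half
#' peak-to-trough excursion over cycles 2--4 (or as many complete cycles as
#' exist in that window), a convention that stays well defined for slowly
#' damped signals and is consistent with normalizing to a control amplitude.
#'
#' @param t time grid (h), strictly increasing; or a `clock_trajectory` in
#'   which case `x` names the species column (default `"P"`).
#' @param x numeric series, or column name when `t` is a trajectory.
#' @return list with `period_h`, `amplitude`, `peak_times`.
#' @export
period_amplitude <- function(t, x = "P") {
  if (inherits(t, "clock_trajectory") || is.data.frame(t)) {
    ser <- t[[x]]
    t <- t$t_h
    x <- ser
  }
  pk <- find_peaks(t, x)
  if (nrow(pk) < 3)
    stop("non-oscillatory: fewer than 3 peaks detected", call. = FALSE)
  tr <- find_peaks(t, -x)
  tr$x <- -tr$x
  use <- pk[-1, , drop = FALSE]
  period <- mean(diff(use$t))
  ## cycles 2-4: peaks 2..4 paired with the next trough
  amps <- c()
  for (k in 2:min(4, nrow(pk))) {
    nxt <- which(tr$t > pk$t[k])
    if (length(nxt))
      amps <- c(amps, (pk$x[k] - tr$x[nxt[1]]) / 2)
  }
  if (!length(amps))
    stop("non-oscillatory: no trough following the retained peaks",
         call. = FALSE)
  list(period_h = period, amplitude = mean(amps), peak_times = pk$t)
}

#' Add white Gaussian measurement noise at a fixed signal-to-noise ratio
#'
#' The noise variance equals the signal's power divided by `snr`,
#' interpreted as a linear power ratio (default 5, not dB). Signal power is
#' the mean square (the usual measured-power convention for a non-zero-mean
#' signal), so a weak oscillation riding on a high baseline receives noise
#' scaled to the baseline and is drowned out, while a large-amplitude
#' oscillation is not.
#'
#' @param signal numeric vector.
#' @param snr linear signal-to-noise power ratio, > 0.
#' @param seed optional integer seed for reproducibility.
#' @return `signal` plus noise.
#' @export
add_noise <- function(signal, snr = 5, seed = NULL) {
  if (is.na(snr) || snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (is.infinite(snr)) return(signal)
  pow <- mean(signal^2)
  if (pow == 0) stop("zero-power signal: cannot set a noise level",
                     call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  signal + rnorm(length(signal), sd = sqrt(pow / snr))
}

## same-length causal FIR pass (zeros assumed before the series start)
fir_causal <- function(b, x) {
  nb <- length(b)
  y <- stats::filter(c(rep(0, nb - 1), x), b,
                     method = "convolution", sides = 1)
  as.numeric(y)[nb:(length(x) + nb - 1)]
}

## zero-phase forward-backward FIR filtering with edge reflection padding
filtfilt_fir <- function(b, x) {
  nb <- length(b)
  npad <- 3 * (nb - 1)
  if (length(x) <= npad) stop("signal too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xx <- c(pre, x, post)
  y <- fir_causal(b, xx)
  y <- rev(fir_causal(b, rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Low-pass filter and standardize a sampled signal
#'
#' Applies the 4-tap moving-average FIR b = (0.2, 0.2, 0.2, 0.2), a = 1
#' forward and backward (zero phase), then standardizes to mean 0 and
#' standard deviation 1. The sampling convention is 15-min samples
#' (fs = 96 per day).
#'
#' @param samples numeric vector (>= 2 days of samples recommended).
#' @param fs sampling frequency (1/day), default 96.
#' @param b FIR coefficients.
#' @return standardized filtered samples; attributes `fs`.
#' @export
preprocess_signal <- function(samples, fs = 96, b = rep(0.2, 4)) {
  y <- filtfilt_fir(b, samples)
  s <- sd(y)
  if (!is.finite(s) || s == 0)
    stop("constant signal after filtering: cannot standardize", call. = FALSE)
  structure((y - mean(y)) / s, fs = fs)
}

#' Periodogram power spectrum
#'
#' @param x numeric vector (assumed mean-removed).
#' @param fs sampling frequency (1/day).
#' @return data frame with `freq` (1/day, DC excluded, up to Nyquist) and
#'   `power`.
#' @export
power_spectrum <- function(x, fs = 96) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  nf <- floor(n / 2)
  data.frame(freq = (1:nf) * fs / n, power = P[2:(nf + 1)])
}

#' Circadian power fraction of a cell population
#'
#' For each cell's (preprocessed) signal, the fraction of total spectral
#' power within a window of half-width `halfwidth` around the population
#' circadian frequency f_C, where f_C maximizes the population-average power
#' in the interval 0.7--1.3 per day. Ranges from 0 (no circadian
#' oscillations) to 1 (perfect sinusoidal circadian oscillations).
#'
#' @param signals numeric matrix (cells in rows) or list of numeric vectors,
#'   all the same length, already filtered/standardized.
#' @param fs sampling frequency (1/day), default 96.
#' @param halfwidth window half-width around f_C (1/day), default 0.1.
#' @return numeric vector of per-cell fractions in \[0, 1\], with attribute
#'   `f_c` (the shared population circadian frequency).
#' @export
circadian_power_fraction <- function(signals, fs = 96, halfwidth = 0.1) {
  if (is.list(signals)) signals <- do.call(rbind, signals)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (nrow(signals) == 0) stop("empty population", call. = FALSE)
  spec <- apply(signals, 1, function(x) power_spectrum(x, fs)$power)
  freq <- power_spectrum(signals[1, ], fs)$freq
  avg <- rowMeans(spec)
  band <- freq >= 0.7 & freq <= 1.3
  if (!any(band)) stop("no spectral estimate in the 0.7-1.3/day interval",
                       call. = FALSE)
  f_c <- freq[band][which.max(avg[band])]
  win <- abs(freq - f_c) <= halfwidth + 1e-12
  frac <- colSums(spec[win, , drop = FALSE]) / colSums(spec)
  structure(as.numeric(frac), f_c = f_c)
}
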