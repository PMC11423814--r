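## Bayesian calibration machinery: reconstruction of luminescence targets
## from reported period/amplitude summaries, the (penalized) likelihood,
## an affine-invariant ensemble MCMC sampler and its convergence diagnostic.

#' Reconstruct a luminescence calibration target
#'
#' Treats the reported oscillation period and amplitude of a condition as
#' normally distributed, draws `n_samples` (T, A) pairs (non-positive
#' periods are rejected and resampled), evaluates the mean-zero cosine
#' waveform A cos(2 pi t / T) at hourly points and returns its Monte Carlo
#' mean and standard deviation. Dephasing across draws makes the envelope
#' of the mean decay over time when T_sd > 0.
#'
#' @param T_mean,T_sd period mean and s.d. (h).
#' @param A_mean,A_sd amplitude mean and s.d. (normalized units).
#' @param n_samples Monte Carlo draws (default 1e6 as in the calibration
#'   procedure; reduce for tests).
#' @param horizon_h fit horizon (h), hourly grid from 0.
#' @param seed RNG seed.
#' @return list with `t_h`, `mu`, `sd`, `n_rejected`.
#' @export
reconstruct_experiment <- function(T_mean, T_sd, A_mean, A_sd,
                                   n_samples = 1e6, horizon_h = 120,
                                   seed = 1) {
  stopifnot(T_sd >= 0, A_sd >= 0, n_samples >= 1)
  set.seed(seed)
  t_h <- seq(0, horizon_h, by = 1)
  sum1 <- sum2 <- numeric(length(t_h))
  n_rej <- 0L
  remaining <- n_samples
  chunk <- 50000L
  while (remaining > 0) {
    m <- min(chunk, remaining)
    Ts <- rnorm(m, T_mean, T_sd)
    bad <- Ts <= 0
    while (any(bad)) {
      n_rej <- n_rej + sum(bad)
      Ts[bad] <- rnorm(sum(bad), T_mean, T_sd)
      bad <- Ts <= 0
    }
    As <- rnorm(m, A_mean, A_sd)
    w <- outer(t_h, Ts, function(t, Tp) cos(2 * pi * t / Tp))
    w <- sweep(w, 2, As, `*`)
    sum1 <- sum1 + rowSums(w)
    sum2 <- sum2 + rowSums(w^2)
    remaining <- remaining - m
  }
  mu <- sum1 / n_samples
  va <- pmax(sum2 / n_samples - mu^2, 0)
  list(t_h = t_h, mu = mu,
       sd = sqrt(va * n_samples / max(1, n_samples - 1)),
       n_rejected = n_rej)
}

#' Normalize a model luciferase trace for comparison with reconstructions
#'
#' Time-shifts the luciferase series to start at the second peak of the
#' simulated dynamics, normalizes by the control-condition amplitude,
#' subtracts its mean over the fit horizon and resamples to the hourly grid.
#'
#' @param traj `clock_trajectory` with an `L` column (see [luciferase()]).
#' @param control_amplitude amplitude of the control-condition trace (> 0).
#' @param horizon_h fit horizon (h).
#' @return list with `t_h` and `L_rel` (mean-zero, hourly).
#' @export
normalize_model_trace <- function(traj, control_amplitude, horizon_h = 120) {
  if (control_amplitude <= 0)
    stop("control amplitude must be > 0", call. = FALSE)
  pk <- find_peaks(traj$t_h, traj$L)
  if (nrow(pk) < 2)
    stop("non-oscillatory: fewer than 2 luciferase peaks", call. = FALSE)
  t0 <- pk$t[2]
  t_h <- seq(0, horizon_h, by = 1)
  if (t0 + horizon_h > max(traj$t_h))
    stop("trajectory too short for the fit horizon after the peak shift",
         call. = FALSE)
  L <- approx(traj$t_h, traj$L, xout = t0 + t_h)$y / control_amplitude
  list(t_h = t_h, L_rel = L - mean(L))
}

#' Build the calibration fit setup
#'
#' Bundles baseline parameters, the names of the free parameters (entries of
#' [circadian_params()] and/or [mechano_params()]) and the control condition
#' used for amplitude normalization.
#'
#' @param mechano,circadian baseline parameter objects.
#' @param theta_names character vector naming the free parameters; names
#'   present in `circadian` are treated as circadian, the rest must be
#'   mechano parameters.
#' @param control `treatment_condition` of the control (untreated glass).
#' @param duration,dt_step DDE simulation controls (h).
#' @return list of class `fit_setup`.
#' @export
fit_setup <- function(mechano, circadian, theta_names,
                      control = treatment_condition(), duration = 240,
                      dt_step = 0.05) {
  is_c <- theta_names %in% names(circadian)
  bad <- theta_names[!is_c & !(theta_names %in% names(mechano))]
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(mechano = mechano, circadian = circadian,
                 theta_names = theta_names, is_circadian = is_c,
                 control = control, duration = duration, dt_step = dt_step),
            class = "fit_setup")
}

apply_theta <- function(setup, theta) {
  m <- setup$mechano; cc <- setup$circadian
  for (j in seq_along(theta)) {
    nm <- setup$theta_names[j]
    if (setup$is_circadian[j]) cc[[nm]] <- theta[j] else m[[nm]] <- theta[j]
  }
  list(mechano = m, circadian = cc)
}

simulate_luciferase <- function(mechano, circadian, condition, duration,
                                dt_step) {
  ms <- steady_state_network(mechano, condition)
  cp <- coupling_rates(ms$yap_nuc, ms$mrtf_nuc, circadian)
  traj <- simulate_clock(circadian, cp, duration = duration, dt_out = 0.25,
                         dt_step = dt_step)
  luciferase(traj, circadian)
}

#' Gaussian log-likelihood of a free-parameter vector
#'
#' Simulates the luciferase reporter for every dataset's condition,
#' normalizes each trace (second-peak shift, control-amplitude scaling,
#' mean subtraction) and sums Gaussian log-densities against the
#' reconstructed mean/s.d. at hourly points. Simulation failure or a
#' non-oscillatory trace yields -Inf.
#'
#' @param theta numeric vector of free parameters (order of
#'   `setup$theta_names`).
#' @param datasets list of calibration datasets, each a list with
#'   `condition`, `t_h`, `mu`, `sd` and `T_exp` (experimental mean period).
#' @param setup a [fit_setup()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(theta, datasets, setup) {
  pars <- apply_theta(setup, theta)
  res <- tryCatch({
    ctrl <- simulate_luciferase(pars$mechano, pars$circadian, setup$control,
                                setup$duration, setup$dt_step)
    a_ctrl <- period_amplitude(ctrl$t_h, ctrl$L)$amplitude
    ll <- 0
    for (ds in datasets) {
      if (any(ds$sd <= 0))
        stop("calibration dataset has non-positive s.d.", call. = FALSE)
      traj <- simulate_luciferase(pars$mechano, pars$circadian, ds$condition,
                                  setup$duration, setup$dt_step)
      nm <- normalize_model_trace(traj, a_ctrl,
                                  horizon_h = max(ds$t_h))
      mod <- approx(nm$t_h, nm$L_rel, xout = ds$t_h)$y
      ll <- ll + sum(stats::dnorm(mod, ds$mu, ds$sd, log = TRUE))
    }
    ll
  }, error = function(e) -Inf)
  res
}

#' Period-penalized log-likelihood
#'
#' Adds to [log_likelihood()] a penalty -eta * sum_i (T_model,i -
#' T_exp,i)^2 over datasets, pulling model oscillation periods toward the
#' experimentally measured ones. Reduces exactly to the plain likelihood at
#' eta = 0.
#'
#' @inheritParams log_likelihood
#' @param eta penalty weight (default 100).
#' @return scalar penalized log-likelihood.
#' @export
penalized_log_likelihood <- function(theta, datasets, setup, eta = 100) {
  stopifnot(eta >= 0)
  base <- log_likelihood(theta, datasets, setup)
  if (!is.finite(base)) return(base)
  pars <- apply_theta(setup, theta)
  pen <- 0
  res <- tryCatch({
    for (ds in datasets) {
      traj <- simulate_luciferase(pars$mechano, pars$circadian, ds$condition,
                                  setup$duration, setup$dt_step)
      Tm <- period_amplitude(traj$t_h, traj$L)$period_h
      pen <- pen + (Tm - ds$T_exp)^2
    }
    base - eta * pen
  }, error = function(e) -Inf)
  res
}

#' Affine-invariant ensemble MCMC (stretch move)
#'
#' Goodman--Weare stretch-move sampler. Walkers are initialized uniformly in
#' the prior box; proposals outside the box have zero posterior and are
#' never accepted.
#'
#' @param log_post function(theta) -> scalar log posterior (up to a
#'   constant).
#' @param lower,upper prior-box bounds (finite, lower < upper).
#' @param n_walkers number of walkers (>= 2 * dim).
#' @param n_steps total steps (default 1000).
#' @param seed RNG seed.
#' @param a stretch-move scale parameter (default 2).
#' @param init optional matrix (n_walkers x dim) of starting positions.
#' @return array (n_walkers x n_steps x dim) with attributes
#'   `acceptance_rate` and `log_post` (n_walkers x n_steps).
#' @export
run_mcmc <- function(log_post, lower, upper, n_walkers = 60, n_steps = 1000,
                     seed = 1, a = 2, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  if (n_walkers < 2 * d)
    stop("need n_walkers >= 2 * dim(theta)", call. = FALSE)
  set.seed(seed)
  if (is.null(init)) {
    init <- matrix(runif(n_walkers * d, rep(lower, each = n_walkers),
                         rep(upper, each = n_walkers)), n_walkers, d)
  }
  pos <- init
  lp <- apply(pos, 1, log_post)
  chains <- array(NA_real_, c(n_walkers, n_steps, d))
  lps <- matrix(NA_real_, n_walkers, n_steps)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (w in seq_len(n_walkers)) {
      other <- sample(seq_len(n_walkers)[-w], 1)
      z <- (1 + (a - 1) * runif(1))^2 / a
      prop <- pos[other, ] + z * (pos[w, ] - pos[other, ])
      lp_prop <- if (any(prop < lower | prop > upper)) -Inf else log_post(prop)
      log_accept <- (d - 1) * log(z) + lp_prop - lp[w]
      if (is.finite(lp_prop) && log(runif(1)) < log_accept) {
        pos[w, ] <- prop
        lp[w] <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    chains[, s, ] <- pos
    lps[, s] <- lp
  }
  if (stats::var(as.numeric(lps[, n_steps])) == 0 && n_walkers > 1)
    warning("all walkers report identical posterior values; ensemble may be stuck")
  structure(chains, acceptance_rate = n_acc / (n_walkers * n_steps),
            log_post = lps)
}

#' Flatten a chain array to post-burn-in draws
#' @param chains array from [run_mcmc()].
#' @param burn_in steps to discard (default 500).
#' @param names optional column names.
#' @return matrix (draws x dim).
#' @export
chain_samples <- function(chains, burn_in = 500, names = NULL) {
  stopifnot(burn_in < dim(chains)[2])
  keep <- chains[, (burn_in + 1):dim(chains)[2], , drop = FALSE]
  out <- matrix(aperm(keep, c(1, 2, 3)), ncol = dim(chains)[3])
  colnames(out) <- names
  out
}

#' Maximum a posteriori draw from a chain
#' @param chains array from [run_mcmc()] (needs the `log_post` attribute).
#' @return numeric vector theta_MAP.
#' @export
chain_map <- function(chains) {
  lps <- attr(chains, "log_post")
  idx <- which(lps == max(lps), arr.ind = TRUE)[1, ]
  chains[idx[1], idx[2], ]
}

#' Integrated autocorrelation time of an ensemble chain
#'
#' Sokal-windowed autocorrelation estimate on the walker-averaged chain,
#' maximized over dimensions. An estimate above `len/50` is flagged
#' unreliable with a warning.
#'
#' @param chains array (walkers x steps x dim) or a numeric vector/matrix
#'   (steps, or steps x dim).
#' @param c_win Sokal window constant (default 5).
#' @return scalar IACT estimate (steps).
#' @export
iact <- function(chains, c_win = 5) {
  x <- if (length(dim(chains)) == 3) apply(chains, c(2, 3), mean)
  else as.matrix(chains)
  n <- nrow(x)
  taus <- apply(x, 2, function(v) {
    v <- v - mean(v)
    if (sd(v) == 0) return(1)
    ac <- acf(v, lag.max = n - 1, plot = FALSE, demean = FALSE)$acf[, 1, 1]
    tau <- 1
    for (m in seq_len(n - 1)) {
      tau <- 1 + 2 * sum(ac[2:(m + 1)])
      if (m >= c_win * tau) break
    }
    max(tau, 1)
  })
  out <- max(taus)
  if (out > n / 50)
    warning("chain too short for a reliable IACT estimate")
  out
}
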