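# Calibration machinery: waveform reconstruction, trace normalization,
# (penalized) likelihood, ensemble MCMC, IACT, Sobol' indices.

setup_small <- fit_setup(mp0, cp0, theta_names = c("kep2_y", "ker2_y"),
                         duration = 192, dt_step = 0.1)

test_that("experiment reconstruction: degenerate case and dephasing", {
  det <- reconstruct_experiment(24, 0, 1, 0, n_samples = 10, horizon_h = 72)
  expect_equal(det$mu, cos(2 * pi * det$t_h / 24), tolerance = 1e-12)
  expect_lt(max(det$sd), 1e-7)  # zero up to floating-point cancellation
  # period spread dephases the mean: late-time envelope shrinks, matching an
  # independent Monte Carlo replica within sampling error
  rec <- reconstruct_experiment(24, 1.5, 1, 0.2, n_samples = 4e4,
                                horizon_h = 120, seed = 2)
  early <- max(abs(rec$mu[rec$t_h <= 24]))
  late <- max(abs(rec$mu[rec$t_h >= 96]))
  expect_lt(late, 0.5 * early)
  set.seed(77)
  Ts <- rnorm(4e4, 24, 1.5); Ts[Ts <= 0] <- 24
  As <- rnorm(4e4, 1, 0.2)
  t_chk <- c(12, 48, 100)
  mu_chk <- sapply(t_chk, function(t) mean(As * cos(2 * pi * t / Ts)))
  expect_equal(rec$mu[match(t_chk, rec$t_h)], mu_chk, tolerance = 0.02)
  # default draw count is one million
  expect_equal(eval(formals(reconstruct_experiment)$n_samples), 1e6)
})

test_that("model-trace normalization shifts to the second peak and centers", {
  # synthetic two-frequency signal with known peak times
  t <- seq(0, 240, by = 0.25)
  L <- 2 + cos(2 * pi * (t - 3) / 24) + 0.2 * cos(4 * pi * (t - 3) / 24)
  traj <- data.frame(t_h = t, L = L)
  nm <- normalize_model_trace(traj, control_amplitude = 1.2, horizon_h = 120)
  expect_equal(mean(nm$L_rel), 0, tolerance = 1e-12)
  # second peak of this signal is at t = 27; the shifted series must start
  # at the signal value there
  expect_equal(nm$L_rel[1] - nm$L_rel[nm$t_h == 24 * 4],
               0, tolerance = 1e-6)
  expect_equal(max(nm$L_rel), (max(L) - mean(L[t >= 27 & t <= 147])) / 1.2,
               tolerance = 1e-2)
  expect_error(normalize_model_trace(traj, 0), "> 0")
  flat <- data.frame(t_h = t, L = exp(-t / 40))
  expect_error(normalize_model_trace(flat, 1), "non-oscillatory")
})

test_that("log-likelihood equals its analytic maximum on self-generated data
          and shifts correctly when sigma doubles", {
  th0 <- c(cp0$kep2_y, cp0$ker2_y)
  ds <- generate_synthetic_calibration(th0, setup_small,
                                       list(cond_glass), noise_sd = 0,
                                       sd_floor = 0.05, horizon_h = 96)
  ll <- log_likelihood(th0, ds, setup_small)
  n_pts <- length(ds[[1]]$t_h)
  expect_equal(ll, -n_pts * log(0.05 * sqrt(2 * pi)), tolerance = 1e-6)
  # doubling all sigmas changes the value by the closed form -N log 2
  ds2 <- ds; ds2[[1]]$sd <- 2 * ds[[1]]$sd
  expect_equal(log_likelihood(th0, ds2, setup_small),
               ll - n_pts * log(2), tolerance = 1e-6)
  # reordering conditions leaves the likelihood unchanged
  ds_two <- generate_synthetic_calibration(th0, setup_small,
                                           list(cond_glass, cond_soft),
                                           noise_sd = 0, horizon_h = 96)
  expect_equal(log_likelihood(th0, ds_two, setup_small),
               log_likelihood(th0, rev(ds_two), setup_small),
               tolerance = 1e-10)
  # a parameter vector that kills oscillations gets -Inf, not an error
  expect_identical(log_likelihood(c(50, 50), ds, setup_small), -Inf)
})

test_that("period penalty vanishes at matching periods and grows with
          mismatch; eta = 0 reduces to the plain likelihood", {
  th0 <- c(cp0$kep2_y, cp0$ker2_y)
  ds <- generate_synthetic_calibration(th0, setup_small, list(cond_glass),
                                       noise_sd = 0, horizon_h = 96)
  base <- log_likelihood(th0, ds, setup_small)
  expect_equal(penalized_log_likelihood(th0, ds, setup_small, eta = 0), base,
               tolerance = 1e-9)
  # T_exp equals the model period here, so the eta = 100 default changes
  # nothing
  expect_equal(penalized_log_likelihood(th0, ds, setup_small), base,
               tolerance = 1e-6)
  expect_equal(eval(formals(penalized_log_likelihood)$eta), 100)
  for (delta in c(0.5, 1, 2)) {
    ds_off <- ds; ds_off[[1]]$T_exp <- ds[[1]]$T_exp + delta
    drop <- base - penalized_log_likelihood(th0, ds_off, setup_small,
                                            eta = 100)
    expect_equal(drop, 100 * delta^2, tolerance = 1e-4)
  }
})

test_that("ensemble sampler recovers a 2-D Gaussian and respects bounds", {
  mu <- c(1, -0.5)
  S_inv <- solve(matrix(c(1, 0.6, 0.6, 1), 2))
  lp <- function(th) -0.5 * drop(t(th - mu) %*% S_inv %*% (th - mu))
  ch <- run_mcmc(lp, lower = c(-6, -6), upper = c(6, 6), n_walkers = 20,
                 n_steps = 600, seed = 9)
  draws <- chain_samples(ch, burn_in = 150)
  expect_equal(colMeans(draws), mu, tolerance = 0.12)
  expect_equal(cov(draws)[1, 2], 0.6, tolerance = 0.15)
  expect_true(all(draws >= -6 & draws <= 6))  # bounds never violated
  expect_error(run_mcmc(lp, c(0, 0), c(1, 1), n_walkers = 3), "n_walkers")
  # printed defaults of the sampling protocol
  expect_equal(eval(formals(run_mcmc)$n_walkers), 60)
  expect_equal(eval(formals(run_mcmc)$n_steps), 1000)
  expect_equal(eval(formals(chain_samples)$burn_in), 500)
})

test_that("IACT is ~1 for iid draws and matches the AR(1) closed form", {
  set.seed(10)
  expect_lt(iact(matrix(rnorm(4000))), 1.6)
  rho <- 0.8
  n <- 60000
  x <- numeric(n)
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1)
  tau <- iact(matrix(x))
  expect_equal(tau, (1 + rho) / (1 - rho), tolerance = 0.3)
  expect_warning(iact(matrix(cumsum(rnorm(200)))), "too short")
})

test_that("Sobol' total-order indices: additive and Ishigami oracles", {
  # additive in one parameter only
  fn1 <- function(X) 3 * X[, 2]
  st <- sobol_total_order(fn1, lower = rep(0, 3), upper = rep(1, 3),
                          n_base = 4096, seed = 2)
  expect_equal(unname(st[2]), 1, tolerance = 0.05)
  expect_lt(max(st[c(1, 3)]), 0.02)
  # Ishigami benchmark, analytic total-order indices (a = 7, b = 0.1)
  a <- 7; b <- 0.1
  fni <- function(X) sin(X[, 1]) + a * sin(X[, 2])^2 +
    b * X[, 3]^4 * sin(X[, 1])
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  ST1 <- (1 / 2 * (1 + b * pi^4 / 5)^2 + 8 * b^2 * pi^8 / 225) / V
  ST2 <- (a^2 / 8) / V
  ST3 <- (8 * b^2 * pi^8 / 225) / V
  sti <- sobol_total_order(fni, lower = rep(-pi, 3), upper = rep(pi, 3),
                           n_base = 2^14, seed = 3)
  expect_equal(as.numeric(sti), c(ST1, ST2, ST3), tolerance = 0.05)
  # NA outputs are tolerated and their fraction reported
  fna <- function(X) ifelse(X[, 1] > 0.95, NA_real_, X[, 1])
  stna <- sobol_total_order(fna, 0, 1, n_base = 2048, seed = 4)
  expect_gt(attr(stna, "na_fraction"), 0.01)
  expect_equal(unname(stna[1]), 1, tolerance = 0.1)
})
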