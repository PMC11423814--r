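# Population sampling, cohort simulation, and the population statistics.

test_that("parameter sampling: degenerate cases, log-normal spread, chains", {
  # sigma = 0 and a single-row chain give identical cells
  ch <- matrix(c(14, 0.25), 1, 2,
               dimnames = list(NULL, c("tau_b", "kd_p")))
  ps <- sample_parameters(mp0, cp0, n = 4, sigma = 0, chain = ch, seed = 3)
  expect_identical(ps[[1]]$mechano, ps[[2]]$mechano)
  expect_identical(ps[[1]]$circadian, ps[[4]]$circadian)
  expect_equal(ps[[1]]$circadian$tau_b, 14)

  # log(k) has standard deviation sigma = 0.2 and exponents stay fixed
  ps <- sample_parameters(mp0, cp0, n = 4000, sigma = 0.2, seed = 5)
  kk <- sapply(ps, function(p) p$mechano$k_sf)
  expect_equal(sd(log(kk)), 0.2, tolerance = 0.03)
  expect_equal(mean(log(kk)), log(mp0$k_sf), tolerance = 0.02)
  expect_true(all(sapply(ps, function(p) p$mechano$n_fak) == mp0$n_fak))

  # joint chain draws preserve row coupling
  ch2 <- cbind(tau_b = c(13, 15), kd_p = c(0.2, 0.3))
  ps <- sample_parameters(mp0, cp0, n = 50, chain = ch2, seed = 6)
  pairs <- unique(t(sapply(ps, function(p)
    c(p$circadian$tau_b, p$circadian$kd_p))))
  expect_true(all(apply(pairs, 1, function(r)
    any(abs(r[1] - ch2[, 1]) < 1e-12 & abs(r[2] - ch2[, 2]) < 1e-12))))

  expect_error(sample_parameters(mp0, cp0, n = 2,
                                 chain = ch2[0, , drop = FALSE]), "empty")
  bad <- ch2; colnames(bad) <- c("tau_b", "nope")
  expect_error(sample_parameters(mp0, cp0, n = 2, chain = bad), "unknown")
})

test_that("cohorts are reproducible and collapse without variability/noise", {
  ps <- sample_parameters(mp0, cp0, n = 6, sigma = 0, sigma_circadian = 0,
                          seed = 1)
  pop <- simulate_population(ps, cond_soft, days = 2, metric_days = 4,
                             snr = Inf, dt_step = 0.05)
  # variability and noise disabled: all kymograph rows identical
  expect_true(all(apply(pop$kymograph, 2, function(col)
    max(col) - min(col) < 1e-12)))
  # full-pipeline reproducibility from the master seed
  ps2 <- sample_parameters(mp0, cp0, n = 8, seed = 42)
  a <- simulate_population(ps2, cond_glass, days = 2, metric_days = 4,
                           dt_step = 0.05)
  ps3 <- sample_parameters(mp0, cp0, n = 8, seed = 42)
  b <- simulate_population(ps3, cond_glass, days = 2, metric_days = 4,
                           dt_step = 0.05)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$kymograph, b$kymograph)
})

test_that("softer substrate lengthens the median period and raises the median
          power fraction (stochastic, fixed seed)", {
  n <- 60
  soft <- simulate_population(sample_parameters(mp0, cp0, n, seed = 11),
                              cond_soft, dt_step = 0.05)
  glass <- simulate_population(sample_parameters(mp0, cp0, n, seed = 12),
                               cond_glass, dt_step = 0.05)
  expect_gt(median(soft$metrics$period_h, na.rm = TRUE),
            median(glass$metrics$period_h, na.rm = TRUE))
  expect_gt(median(soft$metrics$power_fraction, na.rm = TRUE),
            median(glass$metrics$power_fraction, na.rm = TRUE))
  expect_true(all(stats::na.omit(pmin(soft$metrics$power_fraction, 1)) >= 0))
})

test_that("Tukey compact letters separate what must be separated", {
  set.seed(8)
  same <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  lt <- anova_tukey(same)$letters
  expect_true(length(unique(lt)) == 1)  # identical groups share one letter
  # two groups 10 pooled-sd apart at n = 200 get distinct letters
  far <- list(lo = rnorm(200, 0, 1), hi = rnorm(200, 10, 1))
  lt2 <- anova_tukey(far)$letters
  expect_false(any(strsplit(lt2[1], "")[[1]] %in% strsplit(lt2[2], "")[[1]]))
  # mixed case: the middle group shares with both ends
  mid <- list(lo = rnorm(30, 0, 5), mid = rnorm(30, 1, 5),
              hi = rnorm(30, 12, 5))
  lt3 <- anova_tukey(mid)$letters
  shared <- function(a, b)
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  expect_true(shared(lt3["lo"], lt3["mid"]))
  expect_false(shared(lt3["lo"], lt3["hi"]))
  expect_equal(eval(formals(anova_tukey)$alpha), 0.05)
  expect_error(anova_tukey(list(a = rep(1, 5), b = rep(1, 5))), "degenerate")
  expect_error(anova_tukey(list(a = 1:5)), ">= 2 groups")
})

test_that("log-scale Pearson correlation matches a permutation oracle", {
  x <- exp(seq(0.1, 2, length.out = 8))
  y <- 3 + 2 * log(x)
  res <- pearson_log(x, y)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # noisy case: two-sided p from cor.test vs an explicit permutation test
  set.seed(14)
  y2 <- 3 + 1.1 * log(x) + rnorm(8, sd = 1.2)
  res2 <- pearson_log(x, y2)
  r_perm <- replicate(4000, abs(cor(log(x), sample(y2))))
  p_perm <- mean(r_perm >= abs(res2$r))
  expect_lt(abs(res2$p - p_perm), 0.06)
  expect_error(pearson_log(c(-1, 2, 3), 1:3), "positive")
  expect_error(pearson_log(rep(2, 4), 1:4), "zero variance")
})

test_that("power fraction correlates more strongly with YAP/TAZ than with
          MRTF across the treatment panel", {
  conds <- list(
    glass = cond_glass,
    soft = cond_soft,
    kpa1 = treatment_condition(stiffness_kpa = 1),
    dense = treatment_condition(density = "high"),
    area900 = treatment_condition(area_um2 = 900),
    cytd = treatment_condition(cytd_um = 1),
    lat = treatment_condition(lat_um = 0.5),
    bleb = treatment_condition(bleb_um = 10))
  n <- 40
  res <- lapply(seq_along(conds), function(i)
    simulate_population(sample_parameters(mp0, cp0, n, seed = 300 + i),
                        conds[[i]], dt_step = 0.05))
  pf <- sapply(res, function(r) median(r$metrics$power_fraction, na.rm = TRUE))
  ync <- sapply(res, function(r) r$mechano_summary[["yap_nc"]])
  mnc <- sapply(res, function(r) r$mechano_summary[["mrtf_nc"]])
  r_y <- pearson_log(ync, pf)
  r_m <- pearson_log(mnc, pf)
  expect_lt(r_y$r, 0)  # higher nuclear YAP/TAZ, weaker oscillations
  expect_gt(abs(r_y$r), abs(r_m$r))
})
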