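## Cell populations: parameter variability, cohort simulation and the
## population statistics (ANOVA + Tukey compact letters, log-scale Pearson).

## parameters held fixed during population sampling: Hill exponents plus
## bookkeeping/config scalars
.fixed_mechano <- c("n_fak", "n_rock", "n_mdia", "n_lam", "n_mg", "n_y27",
                    "n_bleb", "a_poly", "area_a0", "yap5sa_tot",
                    "lmna_npc_mult")
.fixed_circadian <- c("n_b", "n_p", "n_c")

#' Sample per-cell parameter sets
#'
#' Mechanotransduction parameters are drawn independently from log-normal
#' distributions, k = k_base * exp(sigma * r) with r ~ N(0, 1) and
#' sigma = 0.2 by default; Hill exponents are kept constant. Fitted
#' (circadian and MRTF) parameters are drawn jointly as rows of a
#' post-burn-in MCMC chain when one is supplied, preserving posterior
#' correlations; without a chain they fall back to the same log-normal
#' scheme around the supplied baseline.
#'
#' @param mechano baseline `mechano_params`.
#' @param circadian baseline `circadian_params`.
#' @param n number of cells.
#' @param sigma log-normal standard deviation for mechano parameters
#'   (default 0.2).
#' @param sigma_circadian log-normal standard deviation used for the fitted
#'   clock parameters only when no posterior chain is supplied; the default
#'   0.05 emulates the tightness of a calibrated posterior (a posterior-sd
#'   scale dispersion, not the prior-scale 0.2).
#' @param chain optional matrix of posterior draws (rows = samples, columns
#'   named after `circadian_params` entries), already burn-in-trimmed.
#' @param seed master seed; per-cell seeds are derived from it.
#' @return list of `n` cells, each `list(mechano, circadian, seed)`.
#' @export
sample_parameters <- function(mechano, circadian, n, sigma = 0.2,
                              sigma_circadian = 0.05, chain = NULL,
                              seed = 1) {
  stopifnot(sigma >= 0, n >= 1)
  if (!is.null(chain)) {
    chain <- as.matrix(chain)
    if (nrow(chain) == 0)
      stop("empty posterior chain after burn-in", call. = FALSE)
    bad <- setdiff(colnames(chain), names(circadian))
    if (length(bad))
      stop("unknown chain parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  set.seed(seed)
  vary_m <- setdiff(names(mechano), .fixed_mechano)
  vary_c <- setdiff(names(circadian), .fixed_circadian)
  lapply(seq_len(n), function(i) {
    m <- mechano
    for (nm in vary_m) m[[nm]] <- m[[nm]] * exp(sigma * rnorm(1))
    cc <- circadian
    if (!is.null(chain)) {
      row <- chain[sample.int(nrow(chain), 1), ]
      cc[colnames(chain)] <- as.list(unname(row))
    } else {
      for (nm in vary_c) cc[[nm]] <- cc[[nm]] * exp(sigma_circadian * rnorm(1))
    }
    list(mechano = m, circadian = cc,
         seed = as.integer((seed * 7919 + i * 104729) %% 2147483647L))
  })
}

#' Simulate a cohort of cells under one condition
#'
#' Per cell: mechanotransduction steady state, coupling constants, DDE
#' solve, Gaussian measurement noise (SNR 5 by default), 15-min sampling,
#' zero-phase low-pass filtering and standardization, then period/amplitude
#' (from the noise-free trajectory) and the circadian power fraction
#' (shared population frequency). Individual cell failures are recorded and
#' skipped; more than 10% failures aborts.
#'
#' @param param_sets output of [sample_parameters()].
#' @param condition `treatment_condition`.
#' @param days kymograph span in days after the transient (default 3).
#' @param metric_days analysis window for period and power fraction (days
#'   after the transient; default 12 so that the power-fraction window
#'   spans at least two spectral bins regardless of grid alignment).
#' @param trim_days initial transient discarded before any analysis (the
#'   initial condition starts far from the limit cycle).
#' @param species which clock species feeds the kymograph and power fraction
#'   (default `"R"`, the REV-ERBalpha reporter proxy).
#' @param snr signal-to-noise ratio for measurement noise; `Inf` disables
#'   noise.
#' @param halfwidth power-fraction window half-width (1/day).
#' @param dt_step internal DDE integrator step (h).
#' @return A `population_result`: list with `metrics` (data frame: cell_id,
#'   period_h, amplitude, power_fraction), `kymograph` (cells x time matrix
#'   of the sampled noisy signal), `signals` (standardized filtered
#'   signals), `f_c`, `mechano_summary` (median nuclear YAP/TAZ, MRTF and
#'   N/C ratios across cells), `condition`, `failed`.
#' @export
simulate_population <- function(param_sets, condition, days = 3,
                                metric_days = 12, trim_days = 2,
                                species = "R", snr = 5, halfwidth = 0.1,
                                dt_step = 0.02) {
  n <- length(param_sets)
  dt_out <- 0.25  # 15-min sampling = 96/day
  duration <- (trim_days + max(days, metric_days)) * 24
  nt_kymo <- days * 24 / dt_out + 1
  nt_met <- metric_days * 24 / dt_out + 1
  kymo <- matrix(NA_real_, n, nt_kymo)
  sigs <- matrix(NA_real_, n, nt_met)
  period <- amp <- rep(NA_real_, n)
  ynuc <- mnuc <- ync <- mnc <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    ps <- param_sets[[i]]
    res <- tryCatch({
      ms <- steady_state_network(ps$mechano, condition)
      cp <- coupling_rates(ms$yap_nuc, ms$mrtf_nuc, ps$circadian)
      traj <- simulate_clock(ps$circadian, cp, duration = duration,
                             dt_out = dt_out, dt_step = dt_step)
      keep <- traj$t_h >= trim_days * 24 - 1e-9 &
        traj$t_h <= (trim_days + metric_days) * 24 + 1e-9
      t_met <- traj$t_h[keep]
      x <- traj[[species]][keep]
      noisy <- if (is.finite(snr)) {
        set.seed(ps$seed)
        x + rnorm(length(x), sd = sqrt(mean(x^2) / snr))
      } else x
      pa <- tryCatch(period_amplitude(t_met, x), error = function(e) NULL)
      list(ms = ms, noisy = noisy[seq_len(nt_kymo)],
           std = preprocess_signal(noisy), pa = pa)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      next
    }
    kymo[i, ] <- res$noisy
    sigs[i, ] <- res$std
    ynuc[i] <- res$ms$yap_nuc; mnuc[i] <- res$ms$mrtf_nuc
    ync[i] <- res$ms$yap_nc; mnc[i] <- res$ms$mrtf_nc
    if (!is.null(res$pa)) {
      period[i] <- res$pa$period_h
      amp[i] <- res$pa$amplitude
    }
  }
  if (mean(failed) > 0.10)
    stop(sprintf("%d of %d cells failed to simulate", sum(failed), n),
         call. = FALSE)
  ok <- !failed
  pf <- rep(NA_real_, n)
  pf_ok <- circadian_power_fraction(sigs[ok, , drop = FALSE],
                                    fs = 96, halfwidth = halfwidth)
  pf[ok] <- pf_ok
  structure(list(
    metrics = data.frame(cell_id = seq_len(n), period_h = period,
                         amplitude = amp, power_fraction = pf),
    kymograph = kymo, signals = sigs, f_c = attr(pf_ok, "f_c"),
    mechano_summary = c(yap_nuc = median(ynuc, na.rm = TRUE),
                        mrtf_nuc = median(mnuc, na.rm = TRUE),
                        yap_nc = median(ync, na.rm = TRUE),
                        mrtf_nc = median(mnc, na.rm = TRUE)),
    condition = condition, failed = failed
  ), class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat("<population_result> ", nrow(x$metrics), "cells\n")
  cat(sprintf("  median period: %.2f h  median power fraction: %.3f (f_C = %.3f/day)\n",
              median(x$metrics$period_h, na.rm = TRUE),
              median(x$metrics$power_fraction, na.rm = TRUE), x$f_c))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Groups sharing a letter are not significantly different at level `alpha`
#' according to Tukey's honestly-significant-difference post hoc test after
#' one-way ANOVA. Letters are built with the insert-and-absorb algorithm.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha significance threshold (default 0.05).
#' @return list with `letters` (named character vector), `anova_p`, and
#'   `tukey` (the TukeyHSD table).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L)),
               levels = names(groups)))
  if (sd(df$y) == 0) stop("degenerate (zero-variance) data", call. = FALSE)
  fit <- aov(y ~ g, data = df)
  an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  ## significant pairs
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  sig <- tuk[, "p adj"] < alpha
  nms <- names(groups)
  classes <- list(nms)  # start: everyone together
  for (k in which(sig)) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    new <- list()
    for (cl in classes) {
      if (all(c(a, b) %in% cl)) {
        new <- c(new, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else new <- c(new, list(cl))
    }
    ## absorb classes contained in another
    keep <- rep(TRUE, length(new))
    for (i in seq_along(new)) for (j in seq_along(new)) {
      if (i != j && keep[i] && keep[j] &&
          all(new[[i]] %in% new[[j]]) && length(new[[i]]) < length(new[[j]]))
        keep[i] <- FALSE
    }
    classes <- unique(new[keep])
  }
  ## order classes by the mean of their best group, assign letters
  gm <- vapply(groups, mean, 1)
  ord <- order(vapply(classes, function(cl) min(rank(-gm)[cl]), 1))
  classes <- classes[ord]
  letters_out <- setNames(rep("", length(nms)), nms)
  for (i in seq_along(classes))
    for (g in classes[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  list(letters = letters_out, anova_p = an_p, tukey = tuk)
}

#' Pearson correlation of medians on the log scale
#'
#' Correlates `y` with `log(x)` across condition-level medians, as used to
#' relate the median circadian power fraction to the median N/C ratio.
#'
#' @param x positive predictor medians (N/C ratios).
#' @param y response medians (power fractions).
#' @return list with `r` and two-sided `p` for the null r = 0.
#' @export
pearson_log <- function(x, y) {
  if (length(x) < 3) stop("need >= 3 condition points", call. = FALSE)
  if (any(x <= 0)) stop("x must be positive for the log scale", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance", call. = FALSE)
  ct <- cor.test(log(x), y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
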