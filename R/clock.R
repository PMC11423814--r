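## Three-species delay-differential-equation circadian clock.
##
## B = nuclear BMAL1, P = nuclear PER/CRY, R = nuclear REV-ERBalpha.
## REV-ERBalpha represses BMAL1 expression with delay tau_B; BMAL1 activates
## PER/CRY and REV-ERBalpha expression (delays tau_P, tau_R) under PER/CRY
## self-inhibition; REV-ERBalpha expression is proportional (zeta) to PER/CRY
## expression. Nuclear YAP/TAZ and MRTF steady states add
## condition-dependent expression terms (sums of activating Hill functions
## with exponent 2) to each species.

#' Mechano-coupled expression terms of the clock
#'
#' Computes the condition-dependent expression constants K_eB2, K_eP2 and
#' K_eR2 as sums of activating Hill functions (exponent 2) of steady-state
#' nuclear YAP/TAZ and MRTF.
#'
#' @param y_nuc steady-state nuclear YAP/TAZ concentration (uM), >= 0.
#' @param m_nuc steady-state nuclear MRTF concentration (uM), >= 0.
#' @param params `circadian_params`.
#' @return named numeric vector `c(keb2, kep2, ker2)` (conc/h).
#' @export
coupling_rates <- function(y_nuc, m_nuc, params) {
  if (!is.finite(y_nuc) || !is.finite(m_nuc) || y_nuc < 0 || m_nuc < 0)
    stop("nuclear YAP/TAZ and MRTF inputs must be finite and >= 0",
         call. = FALSE)
  p <- params
  n <- p$n_c
  c(keb2 = p$keb2_y * hill(y_nuc, p$kb_y, n) + p$keb2_m * hill(m_nuc, p$kb_m, n),
    kep2 = p$kep2_y * hill(y_nuc, p$kp_y, n) + p$kep2_m * hill(m_nuc, p$kp_m, n),
    ker2 = p$ker2_y * hill(y_nuc, p$kr_y, n) + p$ker2_m * hill(m_nuc, p$kr_m, n))
}

#' Right-hand side of the clock DDE system
#'
#' Time derivatives of (B, P, R) given the instantaneous state and the
#' delayed states. Each species has an expression term minus first-order
#' decay; the REV-ERBalpha expression term is `zeta` times the PER/CRY
#' expression form evaluated at the tau_R-lagged arguments.
#'
#' @param t time (h); unused (the system is autonomous) but kept for the
#'   standard signature.
#' @param state numeric vector `c(B, P, R)`.
#' @param lagged list with `r_tb` = R(t - tau_B), `b_tp`, `p_tp` = B, P at
#'   t - tau_P and `b_tr`, `p_tr` = B, P at t - tau_R.
#' @param params `circadian_params`.
#' @param coupling coupling constants from [coupling_rates()].
#' @return numeric vector `c(dB, dP, dR)` with attribute `keP` (total
#'   PER/CRY expression rate, used by the luciferase reporter).
#' @export
dde_rhs <- function(t, state, lagged, params, coupling) {
  req <- c("r_tb", "b_tp", "p_tp", "b_tr", "p_tr")
  if (!all(req %in% names(lagged)))
    stop("missing delayed value(s): ",
         paste(setdiff(req, names(lagged)), collapse = ", "), call. = FALSE)
  p <- params
  keb1 <- p$keb0 / (1 + (lagged$r_tb / p$kib)^p$n_b)
  kep1 <- p$kep0 * hill(lagged$b_tp, p$kab, p$n_p) /
    (1 + (lagged$p_tp / p$kip)^p$n_p)
  ker1 <- p$zeta * p$kep0 * hill(lagged$b_tr, p$kab, p$n_p) /
    (1 + (lagged$p_tr / p$kip)^p$n_p)
  d <- c(keb1 + coupling[["keb2"]] - p$kd_b * state[1],
         kep1 + coupling[["kep2"]] - p$kd_p * state[2],
         ker1 + coupling[["ker2"]] - p$kd_r * state[3])
  attr(d, "keP") <- kep1 + coupling[["kep2"]]
  d
}

#' Fixed point of the clock
#'
#' Unique positive steady state (B*, P*, R*) of the DDE system (delayed and
#' instantaneous arguments equal). Reduced to a scalar root-find in P*: the
#' P-balance is strictly decreasing in P once R* and B* are substituted, so
#' the positive root is unique.
#'
#' @param params `circadian_params`.
#' @param coupling coupling constants from [coupling_rates()].
#' @return named numeric vector `c(B, P, R)` with rhs residual below 1e-10.
#' @export
clock_fixed_point <- function(params, coupling) {
  p <- params
  keb2 <- coupling[["keb2"]]; kep2 <- coupling[["kep2"]]
  ker2 <- coupling[["ker2"]]
  r_of_p <- function(P) (p$zeta * (p$kd_p * P - kep2) + ker2) / p$kd_r
  b_of_p <- function(P) {
    R <- r_of_p(P)
    (p$keb0 / (1 + (R / p$kib)^p$n_b) + keb2) / p$kd_b
  }
  g <- function(P) {
    B <- b_of_p(P)
    p$kep0 * hill(B, p$kab, p$n_p) / (1 + (P / p$kip)^p$n_p) + kep2 -
      p$kd_p * P
  }
  p_lo <- max(0, (kep2 - ker2 / p$zeta) / p$kd_p) + 1e-12
  p_hi <- (p$kep0 + kep2) / p$kd_p + 1e-9
  if (g(p_lo) < 0 || g(p_hi) > 0)
    stop("no positive clock fixed point found", call. = FALSE)
  P <- uniroot(g, c(p_lo, p_hi), tol = 1e-14)$root
  fp <- c(B = b_of_p(P), P = P, R = r_of_p(P))
  lag <- list(r_tb = fp[["R"]], b_tp = fp[["B"]], p_tp = fp[["P"]],
              b_tr = fp[["B"]], p_tr = fp[["P"]])
  res <- dde_rhs(0, fp, lag, params, coupling)
  if (max(abs(res)) > 1e-10)
    stop("fixed-point residual above tolerance: ", max(abs(res)),
         call. = FALSE)
  fp
}

#' Simulate the clock DDEs
#'
#' Integrates the clock by the method of steps (fixed-step RK4, cubic-Hermite
#' history interpolation, implemented in C++). Pre-history for t < 0 is
#' constant at the initial condition. By default the initial condition is
#' B0 = 5 B*, P0 = 0.2 P*, R0 = R* from the condition's fixed point.
#'
#' @param params `circadian_params`.
#' @param coupling coupling constants from [coupling_rates()].
#' @param duration simulated time (h); default 6 days.
#' @param dt_out output grid spacing (h), <= 0.25.
#' @param dt_step internal integrator step (h).
#' @param init optional `c(B, P, R)` initial condition.
#' @return A `clock_trajectory`: data frame with columns `t_h`, `B`, `P`,
#'   `R` and `keP` (total PER/CRY expression rate), with the parameters and
#'   coupling attached as attributes.
#' @export
simulate_clock <- function(params, coupling, duration = 144, dt_out = 0.25,
                           dt_step = 0.02, init = NULL) {
  if (dt_out > 0.25 + 1e-12)
    stop("dt_out must be <= 0.25 h", call. = FALSE)
  if (is.null(init)) {
    fp <- clock_fixed_point(params, coupling)
    init <- c(5 * fp[["B"]], 0.2 * fp[["P"]], fp[["R"]])
  }
  par <- c(unlist(params[c("tau_b", "tau_p", "tau_r", "kd_b", "kd_p", "kd_r",
                           "keb0", "kib", "n_b", "kep0", "kab", "kip", "n_p",
                           "zeta")]),
           keb2 = coupling[["keb2"]], kep2 = coupling[["kep2"]],
           ker2 = coupling[["ker2"]])
  out <- .clock_dde_cpp(par, as.numeric(init), duration, dt_out, dt_step)
  traj <- data.frame(t_h = out$t_h, B = out$B, P = out$P, R = out$R,
                     keP = out$keP)
  if (any(!is.finite(unlist(traj))))
    stop("DDE integration failed (non-finite values); check parameters",
         call. = FALSE)
  structure(traj, class = c("clock_trajectory", "data.frame"),
            params = params, coupling = coupling)
}

#' Luciferase reporter dynamics
#'
#' Integrates dL/dt = ke_l * (PER/CRY expression rate) - kd_l * L with
#' L(0) = 0, using the exact exponential update for a piecewise-linear
#' expression input on the trajectory grid.
#'
#' @param traj a `clock_trajectory` containing the `keP` series.
#' @param params `circadian_params`.
#' @return `traj` with an added column `L`.
#' @export
luciferase <- function(traj, params) {
  stopifnot("keP" %in% names(traj))
  k <- params$kd_l
  sc <- params$ke_l
  t <- traj$t_h
  s <- sc * traj$keP
  n <- length(t)
  L <- numeric(n)
  for (i in seq_len(n - 1)) {
    h <- t[i + 1] - t[i]
    m <- (s[i + 1] - s[i]) / h
    e <- exp(-k * h)
    f1 <- (1 - e) / k
    L[i + 1] <- L[i] * e + s[i] * f1 + m * (h / k - f1 / k)
  }
  traj$L <- L
  traj
}

#' Integrate the scalar linear test DDE x'(t) = -a x(t - tau)
#'
#' Validation problem for the method-of-steps integrator: with a = 1 the
#' zero solution is asymptotically stable for tau < pi/2 and a Hopf
#' bifurcation occurs exactly at tau = pi/2 (frequency 1).
#'
#' @param a feedback gain.
#' @param tau delay.
#' @param x0 initial value (constant pre-history).
#' @param duration,dt time span and output step.
#' @return data frame with columns `t` and `x`.
#' @export
simulate_linear_dde <- function(a = 1, tau = pi / 2, x0 = 1,
                                duration = 100, dt = 0.01) {
  x <- .linear_dde_cpp(a, tau, x0, duration, dt)
  data.frame(t = seq(0, by = dt, length.out = length(x)), x = x)
}

#' Write a trajectory to CSV
#' @param traj a `clock_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
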