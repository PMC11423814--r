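## Linear stability analysis of the clock DDEs: characteristic roots of
## det(lambda I - A0 - AB e^(-lambda tau_B) - AP e^(-lambda tau_P)
##     - AR e^(-lambda tau_R)) = 0
## about the fixed point, and the Hopf locus over the nuclear YAP/TAZ--MRTF
## plane.

#' Linearize the clock about its fixed point
#'
#' Analytic partial derivatives of the DDE right-hand side with respect to
#' the instantaneous state (pure decay, -K_d on the diagonal) and each
#' delayed argument, evaluated at the fixed point.
#'
#' @param params `circadian_params`.
#' @param coupling coupling constants from [coupling_rates()].
#' @return list of class `characteristic_problem`: `fp`, matrices `A0`,
#'   `AB`, `AP`, `AR` and `delays = c(tau_b, tau_p, tau_r)`.
#' @export
linearize <- function(params, coupling) {
  p <- params
  fp <- clock_fixed_point(params, coupling)
  B <- fp[["B"]]; P <- fp[["P"]]; R <- fp[["R"]]
  A0 <- diag(c(-p$kd_b, -p$kd_p, -p$kd_r))
  ## d keB1 / dR at lag tau_B
  u <- (R / p$kib)^p$n_b
  dB_dR <- -p$keb0 * p$n_b * u / R / (1 + u)^2
  AB <- matrix(0, 3, 3); AB[1, 3] <- dB_dR
  ## PER/CRY expression partials at lag tau_P (and, scaled by zeta, tau_R)
  hB <- hill(B, p$kab, p$n_p)
  hP <- 1 / (1 + (P / p$kip)^p$n_p)
  dkeP_dB <- p$kep0 * hP * p$n_p * p$kab^p$n_p * B^(p$n_p - 1) /
    (p$kab^p$n_p + B^p$n_p)^2
  v <- (P / p$kip)^p$n_p
  dkeP_dP <- -p$kep0 * hB * p$n_p * v / P / (1 + v)^2
  AP <- matrix(0, 3, 3); AP[2, 1] <- dkeP_dB; AP[2, 2] <- dkeP_dP
  AR <- matrix(0, 3, 3); AR[3, 1] <- p$zeta * dkeP_dB
  AR[3, 2] <- p$zeta * dkeP_dP
  structure(list(fp = fp, A0 = A0, AB = AB, AP = AP, AR = AR,
                 delays = c(tau_b = p$tau_b, tau_p = p$tau_p,
                            tau_r = p$tau_r)),
            class = "characteristic_problem")
}

## characteristic determinant at complex lambda
char_det <- function(problem, lambda) {
  M <- diag(3) * lambda - problem$A0 -
    problem$AB * exp(-lambda * problem$delays[["tau_b"]]) -
    problem$AP * exp(-lambda * problem$delays[["tau_p"]]) -
    problem$AR * exp(-lambda * problem$delays[["tau_r"]])
  M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
}

#' Rightmost characteristic roots of the linearized clock
#'
#' Newton iteration (numerical complex derivative) from a grid of starting
#' points over a rectangle of the complex plane; converged roots are
#' deduplicated, completed with conjugates and sorted by descending real
#' part. The rectangle default covers the slow (circadian-frequency) root
#' pairs that decide stability.
#'
#' @param problem a `characteristic_problem` from [linearize()].
#' @param n_roots number of roots to return.
#' @param re_range,im_range search rectangle (1/h and rad/h).
#' @param n_grid starting-grid resolution per axis.
#' @return complex vector of roots (residual `|det|` below 1e-10), sorted by
#'   real part.
#' @export
rightmost_roots <- function(problem, n_roots = 6, re_range = c(-0.6, 0.4),
                            im_range = c(0, 1.2), n_grid = 14) {
  starts <- as.vector(outer(
    seq(re_range[1], re_range[2], length.out = n_grid),
    1i * seq(im_range[1], im_range[2], length.out = n_grid), `+`))
  eps <- 1e-7
  roots <- complex(0)
  for (s in starts) {
    lam <- s
    ok <- FALSE
    for (it in 1:60) {
      if (!is.finite(Re(lam)) || !is.finite(Im(lam)) || Mod(lam) > 50) break
      f <- char_det(problem, lam)
      df <- (char_det(problem, lam + eps) - char_det(problem, lam - eps)) /
        (2 * eps)
      if (!is.finite(Mod(f)) || !is.finite(Mod(df)) || Mod(df) == 0) break
      step <- f / df
      lam <- lam - step
      if (Mod(step) < 1e-13) { ok <- TRUE; break }
    }
    if (ok && Mod(char_det(problem, lam)) < 1e-10 &&
        Re(lam) >= re_range[1] - 0.2 && Re(lam) <= re_range[2] + 0.2 &&
        abs(Im(lam)) <= im_range[2] + 0.5) {
      if (!length(roots) || min(Mod(roots - lam), Mod(roots - Conj(lam))) > 1e-6)
        roots <- c(roots, if (Im(lam) >= 0) lam else Conj(lam))
    }
  }
  if (!length(roots))
    stop("characteristic root search did not converge from any start point; ",
         "widen re_range/im_range or refine n_grid", call. = FALSE)
  roots <- roots[order(-Re(roots))]
  full <- c(rbind(roots, Conj(roots)))
  full <- full[Im(full) != 0 | !duplicated(Re(full))]
  full[seq_len(min(n_roots, length(full)))]
}

#' Real part of the rightmost characteristic root for a coupling input
#' @param params `circadian_params`.
#' @param coupling coupling constants.
#' @return list with `max_re`, `omega` (imaginary part of the rightmost
#'   root) and `period_h` (2 pi / omega, `NA` for a real root).
#' @export
rightmost_mode <- function(params, coupling) {
  pr <- linearize(params, coupling)
  r <- rightmost_roots(pr, n_roots = 2)
  lam <- r[1]
  list(max_re = Re(lam), omega = abs(Im(lam)),
       period_h = if (Im(lam) != 0) 2 * pi / abs(Im(lam)) else NA_real_)
}

#' Convert an N/C ratio to a nuclear concentration
#'
#' Two-pool conversion: nuclear = total * nc / (1 + nc), used to express the
#' Hopf plane in N/C-ratio coordinates.
#'
#' @param nc N/C ratio (>= 0).
#' @param total total concentration (uM).
#' @return nuclear concentration (uM).
#' @export
nc_to_nuclear <- function(nc, total) total * nc / (1 + nc)

#' Hopf locus over the YAP/TAZ--MRTF plane
#'
#' For each YAP/TAZ N/C grid value, bisects along the MRTF N/C axis for the
#' zero crossing of the rightmost characteristic root's real part. Points
#' below the locus oscillate with sustained amplitude; points above decay
#' toward the fixed point. The oscillation period map 2 pi / Im(lambda) is
#' returned at the locus.
#'
#' @param params `circadian_params`.
#' @param y_nc_grid YAP/TAZ N/C ratio grid.
#' @param m_nc_range MRTF N/C search interval.
#' @param yap_tot,mrtf_tot totals used to convert N/C ratios to nuclear
#'   concentrations (defaults from [mechano_params()]).
#' @param tol bisection tolerance on the N/C ratio.
#' @return data frame with `y_nc`, `m_nc` (critical ratio, `NA` when no sign
#'   change on the interval) and `period_h` at the bifurcation.
#' @export
hopf_locus <- function(params, y_nc_grid = seq(0.02, 0.32, by = 0.03),
                       m_nc_range = c(0.005, 8), yap_tot = 1.4,
                       mrtf_tot = 1.0, tol = 1e-3) {
  max_re_at <- function(y_nc, m_nc) {
    cp <- coupling_rates(nc_to_nuclear(y_nc, yap_tot),
                         nc_to_nuclear(m_nc, mrtf_tot), params)
    rightmost_mode(params, cp)
  }
  out <- lapply(y_nc_grid, function(y) {
    lo <- m_nc_range[1]; hi <- m_nc_range[2]
    f_lo <- max_re_at(y, lo)$max_re
    f_hi <- max_re_at(y, hi)$max_re
    if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
      return(data.frame(y_nc = y, m_nc = NA_real_, period_h = NA_real_,
                        max_re = NA_real_))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (max_re_at(y, mid)$max_re * f_lo <= 0) hi <- mid else lo <- mid
    }
    ## secant polish on Re(lambda) to land on the locus itself
    m0 <- lo; m1 <- hi
    r0 <- max_re_at(y, m0)$max_re; r1 <- max_re_at(y, m1)$max_re
    for (it in 1:8) {
      if (abs(r1 - r0) < 1e-15) break
      m2 <- m1 - r1 * (m1 - m0) / (r1 - r0)
      m2 <- min(max(m2, m_nc_range[1]), m_nc_range[2])
      r2 <- max_re_at(y, m2)$max_re
      m0 <- m1; r0 <- r1; m1 <- m2; r1 <- r2
      if (abs(r1) < 1e-9) break
    }
    md <- max_re_at(y, m1)
    data.frame(y_nc = y, m_nc = m1, period_h = md$period_h,
               max_re = md$max_re)
  })
  res <- do.call(rbind, out)
  if (all(is.na(res$m_nc)))
    message("no Hopf crossing found on the grid (empty locus)")
  res
}
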