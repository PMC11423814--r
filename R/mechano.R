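## Steady-state solution of the reduced YAP/TAZ--MRTF mechanotransduction
## network. Every activation step has the form
##   dX/dt = a(upstream) * (X_tot - X) - d * X
## so its steady state is X* = X_tot * a / (a + d); the cascade is strictly
## feed-forward (FAK -> RhoA -> {ROCK, mDia} -> {myosin, LIMK -> cofilin} ->
## actin -> {E_cyto -> lamin A -> NPC, stress fibers}), so the unique steady
## state is obtained by evaluating closed forms in order. Actin treatment
## variants (cytochalasin D, latrunculin, jasplakinolide) replace the
## baseline polymerization balance with their own closed forms.

hill <- function(x, k, n) {
  xn <- x^n
  xn / (xn + k^n)
}

inhib <- function(conc, k, n) 1 / (1 + (conc / k)^n)

#' Baseline steady-state F-actin
#'
#' Closed form for the polymerization balance
#' dF/dt = A_poly (k_poly G - k_dep F) under mass conservation
#' F + G = Actin_tot, at given polymerization/depolymerization factors.
#'
#' @param params `mechano_params`.
#' @param k_poly,k_dep optional overrides of the lumped polymerization and
#'   depolymerization rate factors; by default computed from `params` at the
#'   fully basal activity level (no mDia enhancement, fully active cofilin).
#' @return F-actin concentration (uM); `Actin_tot - F` is G-actin.
#' @export
factin_baseline <- function(params, k_poly = NULL, k_dep = NULL) {
  if (is.null(k_poly)) k_poly <- params$k_ra0
  if (is.null(k_dep)) k_dep <- params$k_dep0 * (1 + params$k_sev * params$cof_tot)
  if (params$actin_tot <= 0) stop("actin_tot must be > 0", call. = FALSE)
  if (k_poly < 0 || k_dep < 0 || (k_poly + k_dep) == 0)
    stop("degenerate actin rate constants", call. = FALSE)
  params$actin_tot * k_poly / (k_poly + k_dep)
}

#' Steady-state F-actin under cytochalasin D
#'
#' Cytochalasin D caps F-actin (F + C <-> FC, ratio `r_fc`) and dimerizes
#' G-actin with rate proportional to \[C\]\[G\] (CG2 pool, ratio `r_cg`);
#' dimerized G-actin no longer sequesters MRTF. Mass conservation
#' F + G + 2 CG2 + FC = Actin_tot holds exactly.
#'
#' @param params `mechano_params`.
#' @param C cytochalasin D concentration (uM), assumed in excess.
#' @param k_poly,k_dep lumped actin rate factors (defaults as in
#'   [factin_baseline()]).
#' @return list with `F`, `G_free` (MRTF-relevant free G-actin), `CG2`, `FC`.
#' @export
factin_cytochalasin <- function(params, C, k_poly = NULL, k_dep = NULL) {
  if (C < 0) stop("C must be >= 0", call. = FALSE)
  if (is.null(k_poly)) k_poly <- params$k_ra0
  if (is.null(k_dep)) k_dep <- params$k_dep0 * (1 + params$k_sev * params$cof_tot)
  r <- k_poly / k_dep
  G <- params$actin_tot / (1 + r + 2 * params$r_cg * C + params$r_fc * C * r)
  F <- r * G
  if (F < 0 || F > params$actin_tot)
    stop("no physical F-actin root in [0, Actin_tot]", call. = FALSE)
  list(F = F, G_free = G, CG2 = params$r_cg * C * G, FC = params$r_fc * C * F)
}

#' Steady-state F-actin under latrunculin A/B
#'
#' Latrunculin sequesters G-actin (G + L <-> GL, ratio `r_gl`); only free
#' G-actin polymerizes, and the total G pool (free + sequestered) is what
#' sequesters MRTF. Mass conservation G + GL + F = Actin_tot holds exactly.
#'
#' @param params `mechano_params`.
#' @param L latrunculin concentration (uM), assumed in excess.
#' @param k_poly,k_dep lumped actin rate factors.
#' @return list with `F`, `G` (free), `GL`, `G_tot = G + GL`.
#' @export
factin_latrunculin <- function(params, L, k_poly = NULL, k_dep = NULL) {
  if (L < 0) stop("L must be >= 0", call. = FALSE)
  if (is.null(k_poly)) k_poly <- params$k_ra0
  if (is.null(k_dep)) k_dep <- params$k_dep0 * (1 + params$k_sev * params$cof_tot)
  r <- k_poly / k_dep
  G <- params$actin_tot / (1 + params$r_gl * L + r)
  F <- r * G
  if (F < 0 || F > params$actin_tot)
    stop("no physical F-actin root in [0, Actin_tot]", call. = FALSE)
  list(F = F, G = G, GL = params$r_gl * L * G, G_tot = G * (1 + params$r_gl * L))
}

#' Steady-state F-actin under jasplakinolide
#'
#' Jasplakinolide raises the polymerization rate and lowers the
#' depolymerization rate, both with the shared sensitivity `k_jas_half`
#' (K_2,Jas). F(J) is monotone non-decreasing.
#'
#' @param params `mechano_params`.
#' @param J jasplakinolide concentration (uM).
#' @param k_poly,k_dep untreated lumped actin rate factors.
#' @return F-actin concentration (uM).
#' @export
factin_jasplakinolide <- function(params, J, k_poly = NULL, k_dep = NULL) {
  if (J < 0) stop("J must be >= 0", call. = FALSE)
  if (is.null(k_poly)) k_poly <- params$k_ra0
  if (is.null(k_dep)) k_dep <- params$k_dep0 * (1 + params$k_sev * params$cof_tot)
  fj <- J / (J + params$k_jas_half)
  kp <- k_poly * (1 + params$a_jas * fj)
  kd <- k_dep / (1 + params$b_jas * fj)
  params$actin_tot * kp / (kp + kd)
}

#' Contact-area modulation of FAK phosphorylation
#'
#' Restricting the cell-substrate contact area below the control area `A_0`
#' reduces FAK phosphorylation. The phosphorylation rate is scaled by the
#' saturating factor (1 + k_area) (A/A_0) / (A/A_0 + k_area), which equals 1
#' at A = A_0 and is monotone in A.
#'
#' @param params `mechano_params` (must carry `area_a0 > 0`).
#' @param area contact area (um^2).
#' @param stiffness_kpa substrate stiffness at which to report the resulting
#'   steady-state phospho-FAK level (default glass).
#' @return list with `factor` (the phosphorylation-rate scaling) and `fakp`
#'   (steady-state phospho-FAK at that area and stiffness, uM).
#' @export
fak_contact_modulation <- function(params, area, stiffness_kpa = 1e7) {
  if (is.null(params$area_a0) || !is.finite(params$area_a0) ||
      params$area_a0 <= 0)
    stop("control contact area A_0 is unset; set `area_a0` in the parameter table",
         call. = FALSE)
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  rel <- area / params$area_a0
  factor <- (1 + params$k_area) * rel / (rel + params$k_area)
  kphos <- factor * (params$k_f +
                       params$k_sf * stiffness_kpa / (params$c_e + stiffness_kpa))
  list(factor = factor,
       fakp = params$fak_tot * kphos / (kphos + params$k_df))
}

#' Apply a mutation to a mechanotransduction parameter set
#'
#' `"YAP_5SA"` adds a second, phosphorylation-dead YAP species whose total
#' equals the wild-type YAP/TAZ total (doubling overall YAP/TAZ per cell);
#' `"LMNA"` sets the lamin A phosphorylation rate to zero and doubles the
#' opening rate of nuclear pore complexes; `"none"` is the identity.
#'
#' @param params `mechano_params`.
#' @param mutation `"none"`, `"YAP_5SA"` or `"LMNA"`.
#' @return Modified `mechano_params`.
#' @export
apply_mutation <- function(params, mutation) {
  if (!mutation %in% c("none", "YAP_5SA", "LMNA"))
    stop("unknown mutation: ", mutation, call. = FALSE)
  if (mutation == "YAP_5SA") {
    params$yap5sa_tot <- params$yap_tot
  } else if (mutation == "LMNA") {
    params$k_lamphos <- 0
    params$lmna_npc_mult <- 2 * params$lmna_npc_mult
  }
  params
}

## lumped activity factors shared by the algebraic solution and the ODE oracle
mechano_rates <- function(params, condition) {
  p <- params
  dens_fak <- if (condition$density == "high") p$dens_fak_high else 1
  dens_lats <- if (condition$density == "high") p$dens_lats_high else 1
  area <- if (is.na(condition$area_um2)) p$area_a0 else condition$area_um2
  rel <- area / p$area_a0
  f_area <- (1 + p$k_area) * rel / (rel + p$k_area)
  list(
    kphos_fak = f_area * dens_fak *
      (p$k_f + p$k_sf * condition$stiffness_kpa /
         (p$c_e + condition$stiffness_kpa)),
    y27_inhib = inhib(condition$y27_um, p$k_y27_half, p$n_y27),
    bleb_inhib = inhib(condition$bleb_um, p$k_bleb_half, p$n_bleb),
    lats_mult = p$lats_mult * dens_lats
  )
}

## actin branch: returns lumped k_poly/k_dep plus the treatment-resolved
## F, free G and MRTF-sequestering G pool
actin_branch <- function(params, condition, mdia_act, cofa) {
  p <- params
  k_poly <- p$a_poly * (p$k_ra0 + p$alpha_mdia * mdia_act)
  k_dep <- p$a_poly * p$k_dep0 * (1 + p$k_sev * cofa)
  drugs <- c(cytd = condition$cytd_um, lat = condition$lat_um,
             jas = condition$jas_um)
  if (sum(drugs > 0) > 1)
    stop("combined actin-targeting drugs are not supported", call. = FALSE)
  if (drugs[["cytd"]] > 0) {
    st <- factin_cytochalasin(p, drugs[["cytd"]], k_poly, k_dep)
    list(k_poly = k_poly, k_dep = k_dep, F = st$F, G_free = st$G_free,
         g_pool = st$G_free, CG2 = st$CG2, FC = st$FC, GL = 0)
  } else if (drugs[["lat"]] > 0) {
    st <- factin_latrunculin(p, drugs[["lat"]], k_poly, k_dep)
    list(k_poly = k_poly, k_dep = k_dep, F = st$F, G_free = st$G,
         g_pool = st$G_tot, CG2 = 0, FC = 0, GL = st$GL)
  } else if (drugs[["jas"]] > 0) {
    fj <- drugs[["jas"]] / (drugs[["jas"]] + p$k_jas_half)
    kp <- k_poly * (1 + p$a_jas * fj)
    kd <- k_dep / (1 + p$b_jas * fj)
    F <- p$actin_tot * kp / (kp + kd)
    list(k_poly = kp, k_dep = kd, F = F, G_free = p$actin_tot - F,
         g_pool = p$actin_tot - F, CG2 = 0, FC = 0, GL = 0)
  } else {
    F <- p$actin_tot * k_poly / (k_poly + k_dep)
    list(k_poly = k_poly, k_dep = k_dep, F = F, G_free = p$actin_tot - F,
         g_pool = p$actin_tot - F, CG2 = 0, FC = 0, GL = 0)
  }
}

#' Steady state of the mechanotransduction network
#'
#' Evaluates the unique steady state of the reduced 13-ODE network under a
#' treatment condition by setting each differential equation to zero and
#' solving the resulting closed forms along the feed-forward cascade.
#' Mutations carried by the condition are applied to the parameters first.
#'
#' @param params `mechano_params`.
#' @param condition `treatment_condition`.
#' @return An object of class `mechano_state`: steady-state concentrations of
#'   every species (uM), cytosolic stiffness `e_cyto` (kPa), nuclear and
#'   cytosolic YAP/TAZ and MRTF and their N/C ratios.
#' @export
steady_state_network <- function(params, condition) {
  validate_params(params)
  stopifnot(inherits(condition, "treatment_condition"))
  p <- apply_mutation(params, condition$mutation)
  rt <- mechano_rates(p, condition)

  fakp <- p$fak_tot * rt$kphos_fak / (rt$kphos_fak + p$k_df)
  a_rho <- p$k_fkrho * (p$gamma_fak * fakp^p$n_fak + 1)
  rhoa <- p$rho_tot * a_rho / (a_rho + p$k_drho)
  a_rock <- p$k_rrho * rhoa
  rocka <- p$rock_tot * a_rock / (a_rock + p$k_drock)
  rocka_eff <- rocka * rt$y27_inhib
  a_mdia <- p$k_mr * rhoa
  mdiaa <- p$mdia_tot * a_mdia / (a_mdia + p$k_dmdia)
  rock_act <- hill(rocka_eff, p$k_rock_half, p$n_rock)
  mdia_act <- hill(mdiaa, p$k_mdia_half, p$n_mdia)
  a_myo <- p$k_my * (1 + p$xi_myo * rock_act)
  myoa <- p$myo_tot * a_myo / (a_myo + p$k_dmy)
  myoa_eff <- myoa * rt$bleb_inhib
  a_limk <- p$k_lk * (1 + p$xi_limk * rock_act)
  limka <- p$limk_tot * a_limk / (a_limk + p$k_dl)
  ## active cofilin: k_turn (C_tot - C)(k_m + C) = k_cat LIMKA C
  b <- p$k_turn * (p$cof_tot - p$k_mcof) - p$k_catcof * limka
  cofa <- (b + sqrt(b^2 + 4 * p$k_turn^2 * p$cof_tot * p$k_mcof)) /
    (2 * p$k_turn)
  if (cofa < 0 || cofa > p$cof_tot)
    stop("cofilin steady state outside [0, Cof_tot]", call. = FALSE)

  ab <- actin_branch(p, condition, mdia_act, cofa)
  e_cyto <- p$e_c0 + p$e_cf * ab$F
  a_lam <- p$k_lamdeph * hill(e_cyto, p$k_lam_half, p$n_lam)
  lama <- p$lam_tot * a_lam / (a_lam + p$k_lamphos)
  a_npc <- p$k_npc * p$lmna_npc_mult * lama * ab$F * myoa_eff
  npca <- p$npc_tot * a_npc / (a_npc + p$k_rnpc)

  kin_y <- p$k_yin0 + p$k_yin_npc * npca
  kphos_y <- p$k_yphos * rt$lats_mult
  kdeph_y <- p$k_ydephos * ab$F * myoa_eff
  phos_ratio <- if (kdeph_y > 0) kphos_y / kdeph_y else Inf
  if (is.finite(phos_ratio)) {
    yc <- p$yap_tot / (1 + phos_ratio + kin_y / p$k_yout)
    yp <- yc * phos_ratio
    yn <- yc * kin_y / p$k_yout
  } else {
    yc <- 0; yn <- 0; yp <- p$yap_tot
  }
  ## phosphorylation-dead 5SA-YAP species (all dephosphorylated)
  y5c <- p$yap5sa_tot / (1 + kin_y / p$k_yout)
  y5n <- y5c * kin_y / p$k_yout

  kin_m <- p$k_min0 + p$k_min_npc * npca
  seq <- (ab$g_pool / p$k_mg_half)^p$n_mg
  mfree <- p$mrtf_tot / (1 + seq + kin_m / p$k_mout)
  mn <- mfree * kin_m / p$k_mout
  mcyt <- mfree * (1 + seq)

  yap_nuc <- yn + y5n
  yap_cyt <- yp + yc + y5c
  st <- list(
    fakp = fakp, rhoa_gtp = rhoa, rock_a = rocka, rock_a_eff = rocka_eff,
    mdia_a = mdiaa, myo_a = myoa, myo_a_eff = myoa_eff, limk_a = limka,
    cof_a = cofa, f_actin = ab$F, g_actin = ab$G_free, g_pool = ab$g_pool,
    cg2 = ab$CG2, fc = ab$FC, gl = ab$GL,
    k_poly = ab$k_poly, k_dep = ab$k_dep,
    e_cyto = e_cyto, lamin_a = lama, npc_open = npca,
    yap_nuc = yap_nuc, yap_cyt = yap_cyt, yap_phos = yp,
    yap5sa_nuc = y5n, mrtf_nuc = mn, mrtf_cyt = mcyt, mrtf_free = mfree,
    yap_nc = yap_nuc / yap_cyt, mrtf_nc = mn / mcyt
  )
  bad <- names(st)[vapply(st, function(x) !is.finite(x) || x < 0, logical(1))]
  if (length(bad))
    stop("negative or non-finite steady-state concentration(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(st, class = "mechano_state")
}

#' @export
print.mechano_state <- function(x, ...) {
  cat("<mechano_state>\n")
  cat(sprintf("  F-actin: %.3f uM  E_cyto: %.3f kPa\n", x$f_actin, x$e_cyto))
  cat(sprintf("  YAP/TAZ nuclear: %.4f uM (N/C %.3f)\n", x$yap_nuc, x$yap_nc))
  cat(sprintf("  MRTF nuclear: %.4f uM (N/C %.3f)\n", x$mrtf_nuc, x$mrtf_nc))
  invisible(x)
}

#' Export a mechano steady state as a one-row data frame
#' @param state `mechano_state`.
#' @return A one-row data frame with one column per species.
#' @export
mechano_state_row <- function(state) {
  as.data.frame(unclass(state))
}

#' Time derivatives of the reduced mechanotransduction ODE system
#'
#' The kinetic counterpart of [steady_state_network()], used as an
#' independent route to the steady state by time integration. The state
#' vector holds the 13 dynamic species (plus treatment-specific actin pools
#' when a drug is present); conserved partners are eliminated.
#'
#' @param state named numeric vector as produced by [mechano_ode_init()].
#' @param params `mechano_params` (mutation already applied).
#' @param condition `treatment_condition`.
#' @return named numeric vector of d/dt values (per second).
#' @export
mechano_ode_rhs <- function(state, params, condition) {
  p <- apply_mutation(params, condition$mutation)
  rt <- mechano_rates(p, condition)
  s <- as.list(state)
  d <- numeric(length(state)); names(d) <- names(state)

  d["fakp"] <- rt$kphos_fak * (p$fak_tot - s$fakp) - p$k_df * s$fakp
  a_rho <- p$k_fkrho * (p$gamma_fak * s$fakp^p$n_fak + 1)
  d["rhoa"] <- a_rho * (p$rho_tot - s$rhoa) - p$k_drho * s$rhoa
  d["rocka"] <- p$k_rrho * s$rhoa * (p$rock_tot - s$rocka) - p$k_drock * s$rocka
  d["mdiaa"] <- p$k_mr * s$rhoa * (p$mdia_tot - s$mdiaa) - p$k_dmdia * s$mdiaa
  rock_act <- hill(s$rocka * rt$y27_inhib, p$k_rock_half, p$n_rock)
  mdia_act <- hill(s$mdiaa, p$k_mdia_half, p$n_mdia)
  d["myoa"] <- p$k_my * (1 + p$xi_myo * rock_act) * (p$myo_tot - s$myoa) -
    p$k_dmy * s$myoa
  d["limka"] <- p$k_lk * (1 + p$xi_limk * rock_act) * (p$limk_tot - s$limka) -
    p$k_dl * s$limka
  d["cofa"] <- p$k_turn * (p$cof_tot - s$cofa) -
    p$k_catcof * s$limka * s$cofa / (p$k_mcof + s$cofa)

  k_poly <- p$a_poly * (p$k_ra0 + p$alpha_mdia * mdia_act)
  k_dep <- p$a_poly * p$k_dep0 * (1 + p$k_sev * s$cofa)
  if (condition$jas_um > 0) {
    fj <- condition$jas_um / (condition$jas_um + p$k_jas_half)
    k_poly <- k_poly * (1 + p$a_jas * fj)
    k_dep <- k_dep / (1 + p$b_jas * fj)
  }
  if (condition$cytd_um > 0) {
    C <- condition$cytd_um
    G <- p$actin_tot - s$f - 2 * s$cg2 - s$fc
    ## dimerization/capping with unit reverse rates; ratios r_cg, r_fc
    d["f"] <- k_poly * G - k_dep * s$f - p$r_fc * C * s$f + s$fc
    d["cg2"] <- p$r_cg * C * G - s$cg2
    d["fc"] <- p$r_fc * C * s$f - s$fc
    g_pool <- G
  } else if (condition$lat_um > 0) {
    G <- p$actin_tot - s$f - s$gl
    d["f"] <- k_poly * G - k_dep * s$f
    d["gl"] <- p$r_gl * condition$lat_um * G - s$gl
    g_pool <- G + s$gl
  } else {
    G <- p$actin_tot - s$f
    d["f"] <- k_poly * G - k_dep * s$f
    g_pool <- G
  }

  e_cyto <- p$e_c0 + p$e_cf * s$f
  d["lama"] <- p$k_lamdeph * hill(e_cyto, p$k_lam_half, p$n_lam) *
    (p$lam_tot - s$lama) - p$k_lamphos * s$lama
  myo_eff <- s$myoa * rt$bleb_inhib
  d["npca"] <- p$k_npc * p$lmna_npc_mult * s$lama * s$f * myo_eff *
    (p$npc_tot - s$npca) - p$k_rnpc * s$npca

  kin_y <- p$k_yin0 + p$k_yin_npc * s$npca
  kdeph_y <- p$k_ydephos * s$f * myo_eff
  yp <- p$yap_tot - s$yc - s$yn
  d["yc"] <- kdeph_y * yp - p$k_yphos * rt$lats_mult * s$yc -
    kin_y * s$yc + p$k_yout * s$yn
  d["yn"] <- kin_y * s$yc - p$k_yout * s$yn
  if (p$yap5sa_tot > 0) {
    y5c <- p$yap5sa_tot - s$y5n
    d["y5n"] <- kin_y * y5c - p$k_yout * s$y5n
  }
  kin_m <- p$k_min0 + p$k_min_npc * s$npca
  mfree <- (p$mrtf_tot - s$mn) / (1 + (g_pool / p$k_mg_half)^p$n_mg)
  d["mn"] <- kin_m * mfree - p$k_mout * s$mn
  d
}

#' Initial (rest) state for the mechanotransduction ODE oracle
#' @param params `mechano_params`.
#' @param condition `treatment_condition`.
#' @return named numeric vector compatible with [mechano_ode_rhs()].
#' @export
mechano_ode_init <- function(params, condition) {
  p <- apply_mutation(params, condition$mutation)
  s <- c(fakp = 0, rhoa = 0, rocka = 0, mdiaa = 0, myoa = 0, limka = 0,
         cofa = p$cof_tot, f = 0.1 * p$actin_tot, lama = 0, npca = 0,
         yc = 0, yn = 0, mn = 0)
  if (condition$cytd_um > 0) s <- c(s, cg2 = 0, fc = 0)
  if (condition$lat_um > 0) s <- c(s, gl = 0)
  if (p$yap5sa_tot > 0) s <- c(s, y5n = 0)
  s
}

#' Integrate the mechanotransduction ODEs to (near) steady state
#'
#' Fixed-step RK4 integration of [mechano_ode_rhs()]; used as the
#' independent time-integration oracle for the algebraic steady state.
#'
#' @param params `mechano_params`.
#' @param condition `treatment_condition`.
#' @param t_end integration horizon in seconds.
#' @param dt step size in seconds.
#' @return named state vector at `t_end`.
#' @export
simulate_mechano_ode <- function(params, condition, t_end = 5000, dt = 0.1) {
  s <- mechano_ode_init(params, condition)
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- mechano_ode_rhs(s, params, condition)
    k2 <- mechano_ode_rhs(s + dt / 2 * k1, params, condition)
    k3 <- mechano_ode_rhs(s + dt / 2 * k2, params, condition)
    k4 <- mechano_ode_rhs(s + dt * k3, params, condition)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}
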