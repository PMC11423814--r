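## Parameter containers for the mechanotransduction network and the clock.
##
## Parameters are stored as flat named lists with a class attribute, so they
## round-trip losslessly through the CSV table format (columns: name, value,
## units, source, fit_range_lo, fit_range_hi).

#' Default mechanotransduction network parameters
#'
#' Rate constants and conserved totals for the reduced YAP/TAZ--MRTF
#' mechanotransduction network: FAK (de)phosphorylation, the
#' RhoA/ROCK/mDia/LIMK/cofilin/myosin cascade, actin
#' polymerization/depolymerization (`a_poly` sets the overall timescale,
#' which is immaterial at steady state), the cytosolic stiffness law
#' E_cyto(F-actin), lamin A phosphorylation and nuclear pore complex (NPC)
#' opening, YAP/TAZ (de)phosphorylation and nucleo-cytoplasmic transport, and
#' MRTF transport with G-actin sequestration. Units: rates per second,
#' concentrations in uM, stiffness in kPa, areas in um^2.
#'
#' The numerical values form a reconstructed baseline table calibrated so
#' that F-actin, cytosolic stiffness and the YAP/TAZ and MRTF N/C ratios
#' increase monotonically with substrate stiffness over 0.1 kPa--10 GPa, with
#' glass encoded as 1e7 kPa.
#'
#' @param ... name = value overrides of individual parameters.
#' @return A named list of class `mechano_params`.
#' @export
mechano_params <- function(...) {
  p <- list(
    ## FAK module: basal + stiffness-dependent phosphorylation vs dephosphorylation
    fak_tot   = 1.0,    # uM total FAK
    k_f       = 0.015,  # /s basal phosphorylation
    k_sf      = 0.379,  # /s max stiffness-dependent phosphorylation
    c_e       = 8.0,    # kPa half-max stiffness for FAK activation
    k_df      = 0.035,  # /s dephosphorylation
    ## RhoA activation (high cooperativity in phospho-FAK)
    rho_tot   = 1.0,
    k_fkrho   = 0.0168, # /s
    gamma_fak = 20.0,   # uM^-5 FAK feedback strength
    n_fak     = 5,      # exponent (held fixed in population sampling)
    k_drho    = 0.625,  # /s
    ## ROCK and mDia activation by RhoA-GTP
    rock_tot  = 1.0,
    k_rrho    = 0.648,  # /uM/s
    k_drock   = 0.8,    # /s
    mdia_tot  = 0.8,
    k_mr      = 0.002,  # /uM/s
    k_dmdia   = 0.005,  # /s
    ## saturating activity read-outs used downstream
    k_rock_half = 0.3,  # uM half-max of ROCK activity effect
    n_rock      = 2,    # exponent (fixed)
    k_mdia_half = 0.1,  # uM half-max of mDia effect on polymerization
    n_mdia      = 2,    # exponent (fixed)
    ## myosin and LIMK activation downstream of ROCK
    myo_tot   = 5.0,
    k_my      = 0.035,  # /s basal myosin activation
    xi_myo    = 8.0,    # fold enhancement by ROCK
    k_dmy     = 0.067,  # /s
    limk_tot  = 2.0,
    k_lk      = 0.07,   # /s basal LIMK activation
    xi_limk   = 8.0,    # fold enhancement by ROCK
    k_dl      = 2.0,    # /s
    ## cofilin inactivation by LIMK (Michaelis-Menten)
    cof_tot   = 2.0,
    k_turn    = 0.04,   # /s cofilin dephosphorylation (reactivation)
    k_catcof  = 0.34,   # /s LIMK catalytic rate
    k_mcof    = 4.0,    # uM Michaelis constant
    ## actin polymerization balance (Eq 17 form): a_poly sets the timescale
    actin_tot = 17.9,   # uM total actin monomer units
    a_poly    = 1.0,    # overall timescale factor (arbitrary at steady state)
    k_ra0     = 0.07,   # basal polymerization rate factor
    alpha_mdia = 1.3,   # mDia-driven enhancement of polymerization
    k_dep0    = 0.35,   # basal depolymerization rate factor
    k_sev     = 0.8,    # /uM cofilin-severing enhancement of depolymerization
    ## cytosolic stiffness law
    e_c0      = 0.3,    # kPa baseline cytosolic stiffness
    e_cf      = 0.4,    # kPa per uM F-actin
    ## lamin A dephosphorylation driven by cytosolic stiffness
    lam_tot   = 1.0,
    k_lamdeph = 0.06,   # /s max dephosphorylation
    k_lam_half = 3.0,   # kPa half-max stiffness
    n_lam     = 2.6,    # exponent (fixed)
    k_lamphos = 0.01,   # /s lamin A phosphorylation (zeroed by LMNA mutation)
    ## NPC opening driven by lamin A, F-actin and myosin
    npc_tot   = 1.0,
    k_npc     = 0.08,   # /uM^3/s opening rate (doubled by LMNA mutation)
    k_rnpc    = 8.0,    # /s closing rate
    ## YAP/TAZ phosphorylation cycle and transport
    yap_tot   = 1.4,    # uM total YAP/TAZ
    k_yphos   = 0.2,    # /s phosphorylation (zero for the 5SA-YAP species)
    k_ydephos = 0.004,  # /uM^2/s stress-fiber (F x MyoA) driven dephosphorylation
    k_yin0    = 0.0015, # /s NPC-independent nuclear import
    k_yin_npc = 0.04,   # /s per open-NPC nuclear import
    k_yout    = 0.01,   # /s nuclear export
    lats_mult = 1.0,    # LATS-dependent multiplier of k_yphos (density effect)
    ## MRTF transport and G-actin sequestration
    mrtf_tot  = 1.0,    # uM total MRTF
    k_mg_half = 5.0,    # uM G-actin half-sequestration constant
    n_mg      = 2,      # exponent (fixed)
    k_min0    = 0.004,  # /s NPC-independent nuclear import
    k_min_npc = 0.03,   # /s per open-NPC nuclear import
    k_mout    = 0.015,  # /s nuclear export
    ## inhibitor sensitivities
    k_y27_half = 1.0,   # uM Y-27632 half-inhibition of ROCK activity
    n_y27      = 1,
    k_bleb_half = 2.0,  # uM blebbistatin half-inhibition of active myosin
    n_bleb     = 1,
    r_cg       = 0.15,  # /uM cytochalasin D G-actin dimerization ratio (k_dim/k_rdim)
    r_fc       = 0.05,  # /uM cytochalasin D capping ratio (k_cap/k_uncap)
    r_gl       = 1.0,   # /uM latrunculin sequestration ratio (k_lat/k_rlat)
    a_jas      = 10.0,  # max fold-increase of polymerization by jasplakinolide
    b_jas      = 3.0,   # max fold-decrease of depolymerization by jasplakinolide
    k_jas_half = 0.5,   # uM shared jasplakinolide sensitivity (K_2,Jas)
    ## contact area and density effects
    area_a0    = 2500,  # um^2 control contact area (assumed; not printed in the source data)
    k_area     = 1.0,   # saturation constant of the area -> FAK scaling
    dens_fak_high  = 0.6, # FAK phosphorylation factor at high density
    dens_lats_high = 2.0, # LATS multiplier of YAP/TAZ phosphorylation at high density
    ## mutation bookkeeping (set by apply_mutation, not user-facing)
    yap5sa_tot = 0.0,   # uM mutant 5SA-YAP (phosphorylation-dead) species
    lmna_npc_mult = 1.0 # multiplier on NPC opening rate
  )
  override_params(p, list(...), "mechano_params")
}

#' Default circadian clock parameters
#'
#' Delays, decay rates and expression constants of the reduced three-species
#' clock (B = nuclear BMAL1, P = nuclear PER/CRY, R = nuclear REV-ERBalpha)
#' plus the luciferase reporter, and the magnitudes/half-max constants of the
#' YAP/TAZ and MRTF Hill coupling terms (Hill exponent fixed at 2).
#' Time unit: hours. Clock concentrations are in arbitrary units; coupling
#' half-max constants are in uM of nuclear YAP/TAZ or MRTF.
#'
#' Defaults are a reconstructed maximum-a-posteriori-like set calibrated so
#' that the untreated-on-glass condition oscillates with a period close to
#' 24 h and so that nuclear accumulation of YAP/TAZ and MRTF carries the
#' system across a Hopf bifurcation into damped oscillations.
#'
#' @param ... name = value overrides.
#' @return A named list of class `circadian_params`.
#' @export
circadian_params <- function(...) {
  p <- list(
    tau_b = 14.0,   # h delay: REV-ERBa transcription change -> nuclear BMAL1 change
    tau_p = 9.0,    # h delay for PER/CRY
    tau_r = 7.0,    # h delay for REV-ERBa
    kd_b  = 0.12,   # /h decay of nuclear BMAL1
    kd_p  = 0.25,   # /h decay of nuclear PER/CRY
    kd_r  = 0.35,   # /h decay of nuclear REV-ERBa
    kd_l  = 0.08,   # /h decay of cytosolic luciferase
    keb0  = 0.8,    # conc/h max REV-ERBa-repressible BMAL1 expression
    kib   = 0.7,    # conc REV-ERBa inhibition constant of BMAL1 expression
    n_b   = 2,      # exponent of REV-ERBa inhibition (fixed)
    kep0  = 5.0,    # conc/h max BMAL1-driven PER/CRY expression
    kab   = 0.6,    # conc BMAL1 activation constant
    kip   = 0.15,   # conc PER/CRY self-inhibition constant
    n_p   = 2,      # exponent of activation/self-inhibition (fixed)
    zeta  = 1.0,    # proportionality of REV-ERBa to PER/CRY expression
    ## mechano coupling: sums of activating Hill terms, exponent fixed at 2
    keb2_y = 0.03,  # conc/h magnitude, YAP/TAZ -> BMAL1 expression
    kb_y   = 0.35,  # uM half-max nuclear YAP/TAZ
    keb2_m = 0.02,  # conc/h magnitude, MRTF -> BMAL1 expression
    kb_m   = 0.15,  # uM half-max nuclear MRTF
    kep2_y = 0.4,   # conc/h magnitude, YAP/TAZ -> PER/CRY expression (K_eP2,Y)
    kp_y   = 1.08,
    kep2_m = 0.15,  # conc/h magnitude, MRTF -> PER/CRY expression
    kp_m   = 0.45,
    ker2_y = 0.9,   # conc/h magnitude, YAP/TAZ -> REV-ERBa expression
    kr_y   = 0.22,
    ker2_m = 0.2,   # conc/h magnitude, MRTF -> REV-ERBa expression
    kr_m   = 0.30,
    n_c    = 2,     # coupling Hill exponent (fixed at 2)
    ke_l   = 1.0    # luciferase expression scale (relative to PER/CRY expression)
  )
  override_params(p, list(...), "circadian_params")
}

override_params <- function(p, dots, cls) {
  if (length(dots)) {
    nm <- names(dots)
    if (is.null(nm) || any(nm == ""))
      stop("parameter overrides must be named", call. = FALSE)
    bad <- setdiff(nm, names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[nm] <- dots
  }
  structure(p, class = cls)
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, positivity of conserved totals, delays
#' and Hill constants.
#'
#' @param params a `mechano_params` or `circadian_params` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  v <- unlist(params)
  if (any(!is.finite(v)))
    stop("non-finite parameter value(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "), call. = FALSE)
  if (any(v < 0))
    stop("negative parameter value(s): ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  pos <- if (inherits(params, "mechano_params"))
    c("fak_tot", "rho_tot", "rock_tot", "mdia_tot", "myo_tot", "limk_tot",
      "cof_tot", "actin_tot", "yap_tot", "mrtf_tot", "area_a0")
  else
    c("tau_b", "tau_p", "tau_r", "kd_b", "kd_p", "kd_r", "kd_l",
      "kib", "kab", "kip", "zeta")
  bad <- pos[unlist(params[pos]) <= 0]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(params)
}

#' Read a parameter table from CSV
#'
#' Expects columns `name` and `value`; optional columns `units`, `source`,
#' `fit_range_lo`, `fit_range_hi` are carried as attributes. Unknown or
#' duplicated parameter names are errors.
#'
#' @param path CSV file path.
#' @param what `"mechano"` or `"circadian"`.
#' @return A validated parameter object; fitted ranges (where present) in
#'   `attr(, "fit_ranges")`.
#' @export
load_parameter_table <- function(path, what = c("mechano", "circadian")) {
  what <- match.arg(what)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "value")
  if (!all(req %in% names(tab)))
    stop("parameter table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicated parameter name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  base <- if (what == "mechano") mechano_params() else circadian_params()
  bad <- setdiff(tab$name, names(base))
  if (length(bad))
    stop("unknown parameter name(s) in table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  base[tab$name] <- as.numeric(tab$value)
  p <- validate_params(base)
  if (all(c("fit_range_lo", "fit_range_hi") %in% names(tab))) {
    fr <- tab[!is.na(tab$fit_range_lo) & !is.na(tab$fit_range_hi),
              c("name", "fit_range_lo", "fit_range_hi")]
    if (nrow(fr)) attr(p, "fit_ranges") <- fr
  }
  p
}

#' Write a parameter table to CSV
#'
#' Inverse of [load_parameter_table()]; the roundtrip is the identity on
#' values.
#'
#' @param params parameter object.
#' @param path output CSV path.
#' @export
write_parameter_table <- function(params, path) {
  tab <- data.frame(name = names(params),
                    value = unname(unlist(params)),
                    stringsAsFactors = FALSE)
  fr <- attr(params, "fit_ranges")
  if (!is.null(fr)) {
    tab$fit_range_lo <- fr$fit_range_lo[match(tab$name, fr$name)]
    tab$fit_range_hi <- fr$fit_range_hi[match(tab$name, fr$name)]
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
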