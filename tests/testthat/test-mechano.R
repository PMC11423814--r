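# Steady states of the actin treatment variants are verified two ways:
# against mass conservation (exact closed-form identities) and against an
# independent route — bisection on the rate balance, or time integration of
# the corresponding ODEs to their long-time limit.

test_that("baseline F-actin: closed form, conservation and limits", {
  F <- factin_baseline(mp0)
  expect_true(F > 0 && F < mp0$actin_tot)
  # conservation to machine precision
  G <- mp0$actin_tot - F
  expect_equal(F + G, mp0$actin_tot, tolerance = 1e-15)
  # closed form equals the bisection root of the polymerization balance
  kp <- 0.12; kd <- 0.4
  bal <- function(F) kp * (mp0$actin_tot - F) - kd * F
  F2 <- factin_baseline(mp0, k_poly = kp, k_dep = kd)
  expect_equal(F2, uniroot(bal, c(0, mp0$actin_tot), tol = 1e-12)$root,
               tolerance = 1e-9)
  # polymerization -> 0 limit: F -> 0, G -> Actin_tot
  expect_equal(factin_baseline(mp0, k_poly = 0, k_dep = kd), 0)
  expect_error(factin_baseline(mp0, k_poly = 0, k_dep = 0), "degenerate")
})

test_that("cytochalasin D variant: reduction, conservation, directions", {
  # C = 0 reduces exactly to the baseline closed form
  st0 <- factin_cytochalasin(mp0, 0)
  expect_equal(st0$F, factin_baseline(mp0), tolerance = 1e-14)
  expect_equal(st0$G_free, mp0$actin_tot - st0$F, tolerance = 1e-14)
  # conservation F + G + 2 CG2 + FC = Actin_tot, <= 1e-10 relative
  for (C in c(0.3, 1, 4)) {
    st <- factin_cytochalasin(mp0, C)
    tot <- st$F + st$G_free + 2 * st$CG2 + st$FC
    expect_equal(tot, mp0$actin_tot, tolerance = 1e-10)
  }
  # increasing C: both F and free G decrease
  Fs <- sapply(c(0, 0.5, 1, 2, 4), function(C) factin_cytochalasin(mp0, C)$F)
  Gs <- sapply(c(0, 0.5, 1, 2, 4),
               function(C) factin_cytochalasin(mp0, C)$G_free)
  expect_true(all(diff(Fs) < 0))
  expect_true(all(diff(Gs) < 0))
  expect_error(factin_cytochalasin(mp0, -1), ">= 0")
})

test_that("latrunculin variant: reduction, conservation, limits", {
  st0 <- factin_latrunculin(mp0, 0)
  expect_equal(st0$F, factin_baseline(mp0), tolerance = 1e-14)
  expect_equal(st0$G_tot, st0$G, tolerance = 1e-14)
  for (L in c(0.5, 2, 8)) {
    st <- factin_latrunculin(mp0, L)
    expect_equal(st$G + st$GL + st$F, mp0$actin_tot, tolerance = 1e-10)
  }
  # L -> infinity: F -> 0, total G pool -> Actin_tot
  big <- factin_latrunculin(mp0, 1e7)
  expect_lt(big$F, 1e-4 * mp0$actin_tot)
  expect_equal(big$G_tot, mp0$actin_tot, tolerance = 1e-4)
})

test_that("jasplakinolide variant: reduction and monotonicity", {
  expect_equal(factin_jasplakinolide(mp0, 0), factin_baseline(mp0),
               tolerance = 1e-14)
  Js <- seq(0, 5, length.out = 101)
  Fs <- sapply(Js, function(J) factin_jasplakinolide(mp0, J))
  expect_true(all(diff(Fs) >= 0))
  expect_true(all(Fs <= mp0$actin_tot))
})

test_that("network steady state is monotone in substrate stiffness", {
  stiff <- c(0.1, 0.3, 1, 3, 10, 30, 100, 1e3, 1e5, 1e7)
  states <- lapply(stiff, function(E)
    steady_state_network(mp0, treatment_condition(stiffness_kpa = E)))
  for (field in c("f_actin", "e_cyto", "yap_nuc", "yap_nc", "mrtf_nuc",
                  "mrtf_nc")) {
    v <- sapply(states, `[[`, field)
    expect_true(all(diff(v) >= -1e-12), label = paste(field, "monotone"))
  }
})

test_that("default condition object equals explicit all-defaults condition", {
  a <- steady_state_network(mp0, treatment_condition())
  b <- steady_state_network(mp0, treatment_condition(
    stiffness_kpa = 1e7, area_um2 = NA, density = "low", cytd_um = 0,
    lat_um = 0, jas_um = 0, y27_um = 0, bleb_um = 0, mutation = "none"))
  expect_identical(unclass(a), unclass(b))
})

test_that("algebraic steady state equals the long-time ODE limit", {
  for (cond in list(cond_glass, treatment_condition(cytd_um = 1),
                    treatment_condition(lat_um = 1))) {
    st <- steady_state_network(mp0, cond)
    ode <- simulate_mechano_ode(mp0, cond, t_end = 3000, dt = 0.15)
    alg <- c(fakp = st$fakp, rhoa = st$rhoa_gtp, rocka = st$rock_a,
             mdiaa = st$mdia_a, myoa = st$myo_a, limka = st$limk_a,
             cofa = st$cof_a, f = st$f_actin, lama = st$lamin_a,
             npca = st$npc_open, yn = st$yap_nuc - st$yap5sa_nuc,
             mn = st$mrtf_nuc)
    rel <- abs(ode[names(alg)] - alg) / pmax(abs(alg), 1e-12)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("contact-area modulation scales FAK phosphorylation correctly", {
  ctl <- fak_contact_modulation(mp0, mp0$area_a0)
  expect_equal(ctl$factor, 1, tolerance = 1e-14)
  st <- steady_state_network(mp0, treatment_condition())
  expect_equal(ctl$fakp, st$fakp, tolerance = 1e-12)
  # smaller micropatterns give less phospho-FAK, monotone in area
  f900 <- fak_contact_modulation(mp0, 900)$fakp
  f1600 <- fak_contact_modulation(mp0, 1600)$fakp
  expect_lt(f900, f1600)
  expect_lt(f1600, ctl$fakp)
  # micropatterns lower nuclear YAP/TAZ and MRTF versus control
  for (area in c(900, 1600)) {
    sta <- steady_state_network(mp0, treatment_condition(area_um2 = area))
    expect_lt(sta$yap_nuc, st$yap_nuc)
    expect_lt(sta$mrtf_nuc, st$mrtf_nuc)
  }
  bad <- mp0; bad$area_a0 <- NA_real_
  expect_error(fak_contact_modulation(bad, 1000), "A_0")
})

test_that("mutations modify parameters and nuclear localization as defined", {
  expect_identical(apply_mutation(mp0, "none"), mp0)
  expect_error(apply_mutation(mp0, "bogus"), "unknown mutation")
  m5 <- apply_mutation(mp0, "YAP_5SA")
  expect_equal(m5$yap5sa_tot, mp0$yap_tot)
  ml <- apply_mutation(mp0, "LMNA")
  expect_equal(ml$k_lamphos, 0)
  expect_equal(ml$lmna_npc_mult, 2 * mp0$lmna_npc_mult)

  c30 <- treatment_condition(stiffness_kpa = 30)
  wt <- steady_state_network(mp0, c30)
  sa <- steady_state_network(mp0, treatment_condition(
    stiffness_kpa = 30, mutation = "YAP_5SA"))
  lm <- steady_state_network(mp0, treatment_condition(
    stiffness_kpa = 30, mutation = "LMNA"))
  # 5SA: nuclear YAP/TAZ far above wild type; MRTF unchanged
  expect_gt(sa$yap_nuc, 1.5 * wt$yap_nuc)
  expect_equal(sa$mrtf_nuc, wt$mrtf_nuc, tolerance = 1e-12)
  # LMNA: both elevated
  expect_gt(lm$yap_nuc, wt$yap_nuc)
  expect_gt(lm$mrtf_nuc, wt$mrtf_nuc)
})

test_that("cytochalasin D is the unique treatment moving YAP/TAZ and MRTF in
          opposite directions", {
  ctl <- steady_state_network(mp0, cond_glass)
  dirs <- function(cond) {
    st <- steady_state_network(mp0, cond)
    c(sign(st$yap_nuc - ctl$yap_nuc), sign(st$mrtf_nuc - ctl$mrtf_nuc))
  }
  opposite <- function(d) d[1] * d[2] < 0
  expect_true(opposite(dirs(treatment_condition(cytd_um = 1))))
  same_dir <- list(treatment_condition(lat_um = 1),
                   treatment_condition(jas_um = 1),
                   treatment_condition(y27_um = 10),
                   treatment_condition(bleb_um = 10),
                   treatment_condition(area_um2 = 900),
                   treatment_condition(density = "high"),
                   treatment_condition(stiffness_kpa = 1))
  for (cond in same_dir) expect_false(opposite(dirs(cond)))
})
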