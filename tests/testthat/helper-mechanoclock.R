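# shared fixtures for the test suite (built in code, no stored data)

mp0 <- mechano_params()
cp0 <- circadian_params()

cond_glass <- treatment_condition()
cond_soft <- treatment_condition(stiffness_kpa = 0.1)
cond_jas <- treatment_condition(jas_um = 1)

coupling_for <- function(cond, mechano = mp0, circadian = cp0) {
  st <- steady_state_network(mechano, cond)
  coupling_rates(st$yap_nuc, st$mrtf_nuc, circadian)
}

zero_coupling <- c(keb2 = 0, kep2 = 0, ker2 = 0)

# quick per-condition simulation of the clock P series
sim_P <- function(cond, duration = 240, ...) {
  simulate_clock(cp0, coupling_for(cond), duration = duration, ...)
}
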