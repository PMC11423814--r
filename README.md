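# mechanoclock

Cells sense the mechanics of their surroundings — substrate stiffness,
adhesive area, crowding, cytoskeletal drugs — and relay those signals to the
nucleus through the transcriptional co-regulators YAP/TAZ and MRTF. Recent
experiments show that this mechanotransduction axis also perturbs the
cellular circadian clock: softer substrates and cytoskeletal inhibition
lengthen and strengthen PER2 reporter oscillations, while nuclear
accumulation of YAP/TAZ or MRTF (stiff substrates, 5SA-YAP overexpression,
lamin A defects) weakens or abolishes them.

`mechanoclock` implements a coupled computational model of this crosstalk
for computational biologists studying clock mechanosensitivity:

1. **Mechanotransduction network** — a reduced 13-ODE YAP/TAZ–MRTF signaling
   network (FAK → RhoA → ROCK/mDia → myosin, LIMK/cofilin → actin →
   cytosolic stiffness → lamin A → nuclear pore opening) solved *at steady
   state* in closed form for any treatment condition, including closed-form
   F-actin solutions for cytochalasin D (capping + G-actin dimerization),
   latrunculin A/B (G-actin sequestration), jasplakinolide (enhanced
   polymerization), Hill-type ROCK/myosin inhibition (Y-27632,
   blebbistatin), contact-area and cell-density effects, and 5SA-YAP / LMNA
   mutations.
2. **Circadian clock** — a three-species delay differential equation (DDE)
   system for nuclear BMAL1 (*B*), PER/CRY (*P*) and REV-ERBα (*R*):

   ```
   dB/dt = K_eB1(R[t−τ_B]) + K_eB2(Y_nuc, M_nuc) − K_dB·B
   dP/dt = K_eP1(B[t−τ_P], P[t−τ_P]) + K_eP2(Y_nuc, M_nuc) − K_dP·P
   dR/dt = ζ·K_eP1(B[t−τ_R], P[t−τ_R]) + K_eR2(Y_nuc, M_nuc) − K_dR·R
   ```

   where REV-ERBα represses BMAL1 expression (delay τ_B), BMAL1 activates
   PER/CRY under PER/CRY self-inhibition (delay τ_P), and the steady-state
   nuclear YAP/TAZ and MRTF concentrations enter as sums of activating Hill
   terms (exponent 2). A luciferase reporter (dL/dt ∝ PER/CRY expression −
   K_dL·L) connects the model to luminescence recordings. Integration is by
   the method of steps (fixed-step RK4, cubic-Hermite history, in C++).
3. **Analysis layers** — population simulation with log-normal parameter
   variability (σ = 0.2) and measurement noise (SNR 5), the circadian
   **power fraction** (windowed periodogram ratio around the population
   circadian frequency, 0 = arrhythmic, 1 = perfect sinusoid), one-way
   ANOVA + Tukey compact letter displays, log-scale Pearson correlations,
   Gaussian-likelihood Bayesian calibration with a period penalty and an
   affine-invariant ensemble MCMC sampler, total-order Sobol' sensitivity
   indices, and Hopf-bifurcation analysis of the linearized DDE system
   (rightmost characteristic roots, locus over the YAP/TAZ–MRTF N/C plane).

## Worked example

```r
library(mechanoclock)
params <- default_parameter_tables()      # packaged baseline tables

## a soft 0.1 kPa substrate
soft <- treatment_condition(stiffness_kpa = 0.1)
state <- steady_state_network(params$mechano, soft)
state
#> <mechano_state>
#>   F-actin: 1.545 uM  E_cyto: 0.918 kPa
#>   YAP/TAZ nuclear: 0.0124 uM (N/C 0.009)
#>   MRTF nuclear: 0.0232 uM (N/C 0.024)

## couple into the clock and simulate six days
cc <- coupling_rates(state$yap_nuc, state$mrtf_nuc, params$circadian)
traj <- simulate_clock(params$circadian, cc, duration = 144)
period_amplitude(traj, "P")[c("period_h", "amplitude")]
#> period: 25.96 h, amplitude: 1.77

## a 50-cell population on soft substrate vs glass
cells <- sample_parameters(params$mechano, params$circadian, n = 50, seed = 1)
simulate_population(cells, soft)
#> <population_result>  50 cells
#>   median period: 25.67 h  median power fraction: 0.735 (f_C = 0.916/day)
simulate_population(sample_parameters(params$mechano, params$circadian,
                                      n = 50, seed = 2),
                    treatment_condition())   # glass, 10 GPa
#> <population_result>  50 cells
#>   median period: 24.88 h  median power fraction: 0.133 (f_C = 0.916/day)
```

Low mechanical activation (0.1 kPa) leaves nuclear YAP/TAZ and MRTF almost
entirely cytosolic, so the clock runs as a robust ~26 h limit cycle and most
cells keep a high circadian power fraction (0.74). On glass the coupling
terms push the system close to its Hopf bifurcation: oscillations are
smaller, ~1 h faster, and largely drowned by measurement noise (median power
fraction 0.13). The linearization makes the same call from the rightmost
characteristic root:

```r
rightmost_mode(params$circadian, cc)
#> rightmost eigenvalue: 0.0251 + 0.2645i  (oscillatory, period 23.8 h)
```

A thin command-line wrapper covers the common workflows:

```sh
inst/scripts/mechanoclock simulate   --condition glass.json --out traj.csv
inst/scripts/mechanoclock population --condition glass.json --n-cells 200 --seed 1
inst/scripts/mechanoclock stability  --out locus.csv
inst/scripts/mechanoclock calibrate  --scaled --out map.json
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's spectral calibration
anchor from scratch — it generates a noiseless 24-h sinusoid sampled every
15 minutes for six days, runs it through the packaged filtering /
standardization / power-fraction pipeline, and writes the resulting value as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

- `R/mechano.R` — steady-state network and the ODE oracle
- `R/clock.R`, `src/dde.cpp` — DDE clock and method-of-steps integrator
- `R/metrics.R` — period/amplitude, noise, filtering, power fraction
- `R/population.R` — cohorts, ANOVA/Tukey letters, log-scale Pearson
- `R/calibration.R`, `R/sobol.R` — likelihoods, ensemble MCMC, IACT, Sobol'
- `R/stability.R` — linearization, characteristic roots, Hopf locus
- `R/params.R`, `R/condition.R`, `R/fixtures.R` — parameter tables,
  treatment conditions, packaged fixtures
- `vignettes/mechanoclock-methods.Rmd` — model description, assumptions and
  numerical choices
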