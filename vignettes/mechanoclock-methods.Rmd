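---
title: "Modeling mechanotransduction control of the cellular circadian clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mechanotransduction control of the cellular circadian clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanoclock)
```

## The model

`mechanoclock` couples two timescale-separated systems. Mechanotransduction
operates on minutes: adhesion signaling, cytoskeletal remodeling and
nucleo-cytoplasmic shuttling settle to a steady state long before circadian
gene expression changes appreciably. The clock operates on hours to days.
The package therefore computes the *steady-state* nuclear concentrations of
YAP/TAZ and MRTF for a given mechanical/pharmacological condition and feeds
them as constant inputs into a delay-differential-equation (DDE) model of
the core clock.

### Mechanotransduction at steady state

The reduced network has 25 species and, after eliminating conserved
partners, 13 dynamic states. Every activation step is of the form
`dX/dt = a(upstream) (X_tot − X) − d X`, so its steady state is
`X* = X_tot a/(a + d)` and the strictly feed-forward cascade can be solved
by evaluating closed forms in order:

- **FAK** phosphorylation rises with substrate stiffness `E` through a
  saturating law `E/(C_E + E)` (half-max `c_e`, default 8 kPa). Contact-area
  restriction and high cell density scale the phosphorylation rate down.
- **RhoA** activation amplifies phospho-FAK with fifth-power cooperativity;
  RhoA-GTP activates **ROCK** and **mDia**.
- ROCK activates **myosin** and **LIMK**; LIMK inactivates the
  F-actin-severing **cofilin** via Michaelis–Menten kinetics (the one step
  whose steady state is a quadratic root, taken on the physical branch
  `[0, Cof_tot]`).
- **Actin**: `dF/dt = A_poly (k_poly G − k_dep F)` with mass conservation
  `F + G = Actin_tot`. `A_poly` only sets the timescale and cancels at
  steady state. `k_poly` grows with mDia activity; `k_dep` grows with active
  cofilin.
- **Cytosolic stiffness** is affine in F-actin; it drives lamin A
  dephosphorylation (exponent 2.6), which — together with F-actin and active
  myosin — opens **nuclear pore complexes** (NPCs).
- **YAP/TAZ** cycles between phosphorylated-cytosolic,
  dephosphorylated-cytosolic and nuclear pools; dephosphorylation is
  stress-fiber driven (∝ F·myosin), import has an NPC-dependent and a small
  NPC-independent component. **MRTF** import is analogous, but its cytosolic
  pool is sequestered by G-actin with a squared saturation term
  `(G/K_MG)^2`.

Drug treatments replace the actin balance with their own closed forms, all
of which conserve actin mass exactly:

- **Cytochalasin D** caps filaments (`F + C ⇌ FC`) and dimerizes G-actin
  with rate ∝ `[C][G]`; conservation is `F + G + 2 CG₂ + FC = Actin_tot` and
  dimerized G-actin no longer sequesters MRTF. This makes cytochalasin D the
  unique treatment that lowers nuclear YAP/TAZ while *raising* nuclear MRTF.
- **Latrunculin** sequesters G-actin (`G + L ⇌ GL`); the full pool
  `G_tot = G + GL` sequesters MRTF, so both nuclear read-outs fall.
- **Jasplakinolide** raises `k_poly` and lowers `k_dep` with a shared
  sensitivity constant, driving F-actin (and both nuclear read-outs) up.
- **Y-27632** and **blebbistatin** act as Hill-type inhibitions of ROCK
  activity and active myosin respectively.

Mutations modify parameters: **5SA-YAP** adds a phosphorylation-dead YAP
species whose total equals the wild-type total (doubling YAP/TAZ per cell);
**LMNA** sets lamin A phosphorylation to zero and doubles the NPC opening
rate, elevating both nuclear YAP/TAZ and MRTF.

The full algebraic steady-state expressions and parameter tables this
network descends from are not redistributable, so the equations here are a
documented reconstruction that honors every structural constraint
(conservation laws, cascade topology, drug mechanisms, mutation
definitions), and every closed form is verified in the test suite against
time integration of the corresponding kinetic ODEs (agreement ≤ 1e-4
relative, typically ~1e-10).

### The clock DDEs

Three nuclear species — BMAL1 (`B`), PER/CRY (`P`), REV-ERBα (`R`) — evolve
under delayed expression terms minus first-order decay:

- REV-ERBα represses BMAL1 expression with delay `τ_B` (default 14 h; the
  measured lag between *Bmal1* transcription and nuclear BMAL1 is 12–16 h),
  as an inhibitory Hill function of `R(t − τ_B)`.
- BMAL1 activates PER/CRY expression, under PER/CRY self-inhibition, with
  delay `τ_P` (default 9 h; measured 6–9 h).
- REV-ERBα expression is proportional (factor `ζ`) to the PER/CRY
  expression form evaluated at lag `τ_R` (default 7 h), reflecting shared
  E-box regulation.
- A luciferase reporter integrates the PER/CRY expression rate with decay
  `K_dL` and `L(0) = 0`.

Nuclear YAP/TAZ and MRTF add condition-dependent expression constants
`K_eB2`, `K_eP2`, `K_eR2`, each a sum of two activating Hill terms with the
exponent fixed at 2. Raising these constants pushes the fixed point into a
regime where the repressive feedback saturates, and the limit cycle dies in
a supercritical Hopf bifurcation — the core mechanism by which mechanical
activation disrupts the clock.

### Parameter defaults

The packaged baseline tables (`inst/extdata/*.csv`) are the package's own
calibration of the reconstructed model to the qualitative and quantitative
anchors the source literature states:

- untreated cells on glass oscillate with a period close to one day;
- F-actin, cytosolic stiffness, nuclear YAP/TAZ and nuclear MRTF increase
  monotonically with substrate stiffness;
- softer substrates lengthen the period (≈ +1–2 h from glass to 0.1 kPa)
  and increase amplitude;
- jasplakinolide-level nuclear accumulation produces decaying oscillations,
  and the Hopf bifurcation lies between the control and
  jasplakinolide/mutant conditions;
- 5SA-YAP and LMNA cohorts on 30 kPa substrates lose circadian power, the
  5SA effect being the stronger, and stiffness reduction (3 kPa for LMNA,
  0.3 kPa for 5SA-YAP) rescues a wild-type-like power fraction.

These anchors over-determine the qualitative geometry but not individual
rate constants; users fitting their own data should treat the fitting
ranges in the circadian table as priors, as the calibration module does.

## Numerical choices

**DDE integration.** Method of steps with fixed-step classical RK4
(default internal step 0.02 h) and cubic-Hermite interpolation of the
stored solution for delayed lookups. All delays (≥ 4 h) far exceed the step
size, so delayed arguments always fall in completed history and no implicit
iteration is needed. Pre-history for `t < 0` is constant at the initial
condition — the convention of standard DDE solvers; the default initial
condition `B₀ = 5B*, P₀ = 0.2P*, R₀ = R*` is built from the fixed point.
Halving the step changes period estimates by < 0.1% (tested). The
integrator is validated against the scalar linear test DDE
`x′(t) = −x(t − τ)`, which is neutrally stable exactly at `τ = π/2` with
frequency 1.

**Fixed point.** The three steady-state equations reduce to a scalar
root-find in `P*` whose residual function is strictly decreasing, so the
positive fixed point is unique; it is polished to residual ≤ 1e-10.

**Luciferase.** The reporter ODE is integrated exactly for piecewise-linear
expression input (exponential integrator), so its accuracy is limited only
by the trajectory grid.

**Linear stability.** The characteristic function
`det(λI − A₀ − A_B e^{−λτ_B} − A_P e^{−λτ_P} − A_R e^{−λτ_R})` uses analytic
Jacobian blocks (finite-difference-verified). Rightmost roots are found by
Newton iteration from a grid of complex starting points over the rectangle
that contains the slow circadian modes; DDEs have infinitely many roots but
only the rightmost pair decides stability. The Hopf locus over the
YAP/TAZ–MRTF N/C plane is traced by per-column bisection plus a secant
polish to |Re(λ)| < 1e-6. N/C ratios convert to nuclear concentrations via
`nuclear = total·nc/(1 + nc)`.

**Power fraction.** The sampled signal (15-min grid, `f_S` = 96/day) is
low-pass filtered with the zero-phase forward–backward 4-tap FIR
`b = (0.2, 0.2, 0.2, 0.2), a = 1`, standardized to mean 0 / s.d. 1, and
analyzed with a plain periodogram. The per-cell fraction is the spectral
mass within ±0.1/day (configurable half-width; the reference description
leaves the "close window" unspecified) of the population frequency `f_C`,
the maximizer of the population-average power in 0.7–1.3/day, over the
total power up to Nyquist. Two practical choices matter:

- *Noise scaling.* The SNR of 5 is a linear power ratio with signal power
  defined as the mean square (the standard measured-power convention). This
  matters: weak oscillations riding on a high baseline receive noise scaled
  to the baseline and are genuinely drowned out, which is what produces the
  low power fractions of stiff-substrate and mutant cohorts. Scaling noise
  to the variance instead would make the statistic amplitude-invariant.
- *Window length.* Population metrics use a 12-day analysis window (after
  discarding a 2-day transient; kymographs display 3 days). With windows
  much shorter than ~10 days the ±0.1/day integration window spans less
  than one DFT bin and the statistic degenerates into a measure of how
  close a condition's frequency happens to sit to the frequency grid.

**Population variability.** Mechanotransduction parameters are drawn
log-normally, `k = k̄·exp(σ r)` with `σ = 0.2`; Hill exponents stay fixed.
Fitted clock parameters are drawn jointly from posterior chain rows when a
chain is available (preserving correlations); without a chain they fall
back to a log-normal spread of `σ = 0.05`, emulating posterior tightness
rather than prior width — delays drawn at σ = 0.2 would scatter periods far
outside the circadian band, which no calibrated posterior would do.
Per-cell seeds are derived deterministically from the master seed, making
the whole pipeline bit-reproducible.

**Calibration.** Experimental luminescence targets are reconstructed from
reported period/amplitude summaries by Monte Carlo: `(T, A)` pairs are drawn
normally (non-positive periods rejected and redrawn; one million draws by
default) and the mean-zero cosine `A·cos(2πt/T)` is averaged at hourly
points — period spread dephases the mean, so the reconstructed envelope
decays realistically. Model traces are time-shifted to their second
luciferase peak, normalized by the control amplitude and mean-centered
before entering a Gaussian log-likelihood. Because the peak shift is
undefined for non-oscillatory parameter sets, such draws receive −∞ rather
than a soft penalty. The penalized objective subtracts
`η·Σ(T_model − T_exp)²` (squared mismatch; `η = 100`), reducing exactly to
the plain likelihood at `η = 0`. Sampling uses a Goodman–Weare stretch-move
ensemble (60 walkers × 1000 steps, 500 burn-in by default); convergence is
diagnosed with the Sokal-windowed integrated autocorrelation time.
Total-order Sobol' indices use the Saltelli/Jansen estimator with uniform
marginals over the fitting ranges, with NA-aware averaging for
non-oscillatory draws.

## What the synthetic data do and do not establish

The packaged calibration summary table is a *synthetic stand-in*
(`synthetic_calibration_summaries.csv`): the original per-condition
period/amplitude measurements are not redistributable, so the table encodes
only the reported qualitative trends at realistic magnitudes. Green
calibration tests therefore establish that the machinery recovers known
ground truth from data *generated by this model* (parameter-recovery tests)
and that the likelihood behaves analytically — they do not establish fit
quality against the real measurements. Likewise, population-level tests
establish the model's directional predictions under the stated variability
scheme, not the exact violin shapes of the source figures.

## Known limitations

- The mechanotransduction equations are reconstructions constrained by
  structure rather than transcriptions of previously published expressions;
  absolute concentrations should not be over-interpreted.
- Time-resolved mechanotransduction (and clock→mechanics feedback) is out
  of scope: inputs to the clock are steady states.
- Combined actin-targeting drugs (e.g. cytochalasin D + latrunculin) are
  rejected rather than modeled.
- The power fraction inherits the leakage behavior of the plain
  periodogram; comparisons across analysis-window lengths are not
  meaningful.
- Cell-to-cell coupling/synchronization is absent by design — cells are
  independent.
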