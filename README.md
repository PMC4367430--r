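# ohkin

Kinetics and dosimetry of hydroxyl radicals (OH•) in liquids exposed to a
nonthermal atmospheric-pressure plasma jet.

When an argon plasma jet strikes a biosolution, UV photons emitted by
excited reactive species at the surface (mainly the 309 nm OH band, ~4 eV)
propagate into the liquid and photolyse water and hydroxide, generating OH•
below the surface. `ohkin` models that chain end to end for plasma-medicine
researchers who need absolute OH• densities, lifetimes and cell-level dose
estimates from their spectroscopic measurements:

* **Reaction-network kinetics** — OH• loss channels
  (OH + OH → H₂O₂ at k = 1.78×10⁻¹¹ cm³/s, OH + H₂O₂ → HO₂ + H₂O at
  1.7×10⁻¹², the three-body recombination folded to 2.2×10⁻¹¹ at
  M = 2.5×10¹⁹ cm⁻³, plus a secondary loss channel at 2×10⁻¹²), integrated
  with a stiff solver, with continuous-photolysis and pulsed source terms
  and a hydroxide-photodetachment source (OH⁻ + γ → OH• + e⁻, 2.4 eV
  threshold).
* **Lifetime law** — for quadratic loss dn/dt = −α n², the density follows
  n(t) = n₀/(1 + α n₀ t) and the lifetime is **τ = 2/(α n₀)** with
  α_OH = 2.3×10⁻¹¹ cm³/s: denser OH• populations die faster. Lifetimes are
  extracted from measured traces by e-folding or hyperbolic fitting.
* **UV absorption spectroscopy** — Beer–Lambert inversion
  N = ln(I₀/I_V)/(σx) with σ = 0.6×10⁻¹⁶ cm² and x = 1 cm, plus
  exponential depth-attenuation fitting N(z) = G₀e^(−μz) and emission-line
  assignment.
* **Cell dose** — membrane field E = ΔV/d, electric stress ½Kε₀E², the
  secondary-electron-emission coefficient γ = (I_t − I_i)/I_i, discharge
  power, and the **nT criterion**: OH• density × effective exposure time
  against the apoptosis threshold for adherent H460 cells.
* **Synthetic data** — seeded generators for decay traces, pulse trains,
  depth datasets and pH-current series with embedded ground truth.

## Worked example

```r
library(ohkin)

# Theory-vs-experiment lifetimes for the depth-resolved densities
cmp <- compare_theory_experiment(
  n0 = c(4.2, 1.8, 0.8) * 1e16,           # cm^-3 at 2/4/6 mm in DI water
  tau_experimental = c(3.15, 3.61, 3.92) * 1e-6)
round(cmp$tau_theory_s * 1e6, 2)
#> [1]  2.07  4.83 10.87        # microseconds: tau = 2/(alpha*n0)

# The integrated network reproduces the closed form
tr <- simulate(oh_recombination_network(alpha_oh()),
               kinetic_state(0, c(OH = 4.2e16, H2O2 = 0)),
               t_grid = seq(0, 2e-5, length.out = 101))
max(abs(tr$OH - analytic_decay(4.2e16, alpha_oh(), tr$time_s)) / 4.2e16)
#> [1] 2.190994e-09

# Absolute density from a UV absorption reading
m <- absorption_measurement(I0 = 1, IV = 0.0805, path_cm = 1,
                            sigma_cm2 = 0.6e-16)
density_from_absorption(m)
#> [1] 4.199163e+16             # cm^-3

# Depth attenuation of the DI-water profile
fit_attenuation(depth_profile(c(2, 4, 6), c(4.2e16, 1.3e16, 0.8e16), "DI"))
#> <attenuation_model: G0 = 8.58e+16 cm^-3, mu = 4.15 cm^-1, log-rms = 0.162>

# Does a 60 s treatment at each depth cross the apoptosis threshold?
T_eff <- effective_exposure_time(60, 35000, 3.15e-6)   # duty-cycled: 6.6 s
dose_criterion(c(1.9e16, 0.5e16, 0.13e16), T_eff, exposure = 60)$apoptotic
#> [1]  TRUE  TRUE FALSE        # apoptosis at 2 and 4 mm, not at 6 mm
```

The first block shows the lifetime law's central prediction: theory says
τ falls from 10.9 μs to 2.1 μs as the initial density rises from 0.8 to
4.2×10¹⁶ cm⁻³, while the measured lifetimes move the opposite way with
depth — the comparison table exists to make that tension visible. The dose
block classifies the three measurement depths: only the 6 mm position,
where the density (0.13×10¹⁶ cm⁻³) sits below the 0.3×10¹⁶ cm⁻³ threshold,
is predicted non-apoptotic.

A command-line wrapper is installed at `inst/cli/ohkin.R` with subcommands
`simulate`, `lifetime`, `invert`, `depth-fit`, `dose`, `power` and `synth`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ohkin.R", package="ohkin"))')" \
  lifetime --n0 4.2e16,1.8e16,0.8e16 --out table.csv
```

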