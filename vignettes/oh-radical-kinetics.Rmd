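---
title: "Modelling hydroxyl radical generation, loss and dose in plasma-treated liquids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydroxyl radical generation, loss and dose in plasma-treated liquids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohkin)
```

## The physical picture

A needle-type argon plasma jet driven by a ~1 kV square pulse at 35 kHz
bombards the surface of a liquid (deionised water, PBS or culture medium).
Excited reactive species at the plasma–liquid interface emit UV between
~220 nm (~5.6 eV) and 309 nm (~4 eV); these photons propagate into the
liquid, where they photolyse water and photodetach hydroxide
(OH⁻ + γ → OH• + e⁻, threshold 2.4 eV), sustaining a population of
hydroxyl radicals well below the surface. OH• is the dominant reactive
oxygen species in this system; its density and residence time at the depth
of adherent cells set the biological dose.

`ohkin` implements that chain as four connected models, each with the
estimator needed to confront it with spectroscopic data.

## The kinetic model

### Loss channels and rate convention

OH• disappears by self-recombination and by reaction with its own product:

| reaction | k (cm³ s⁻¹) |
|---|---|
| OH + OH → H₂O₂ (ambient air) | 1.78 × 10⁻¹¹ |
| OH + H₂O₂ → HO₂ + H₂O | 1.7 × 10⁻¹² |
| OH + OH + M → H₂O₂ + M (folded) | 2.2 × 10⁻¹¹ |
| secondary OH loss channel | 2 × 10⁻¹² |

The three-body reaction is stored as an effective two-body coefficient
folded at a fixed third-body density M = 2.5 × 10¹⁹ cm⁻³ (one atmosphere);
M is overridable on the network. The secondary loss channel's rate
coefficient is reported in the source literature without resolvable
products, so the default network uses a generic atom-balanced channel
(OH + OH → H₂O + O); the YAML config format accepts arbitrary replacement
chemistry rather than inventing any.

All rate coefficients follow the **density-loss convention**: for a
reaction with event rate $R = k \prod_j n_j^{s_j}$, the lead reactant
loses density at exactly $R$ — the per-event consumption factor is
absorbed into $k$. Each species $i$ changes by $(p_i - s_i)\,R/s_{\max}$,
which conserves atoms exactly. Under this convention the OH balance for
pure recombination reads

$$\frac{dn}{dt} = -\alpha_{\mathrm{OH}}\, n^2,$$

and the package's default effective coefficient is
$\alpha_{\mathrm{OH}} = 2.3\times10^{-11}\ \mathrm{cm^3\,s^{-1}}$
(`alpha_oh()`). Note a deliberate choice here: the folded three-body
coefficient plus the secondary channel sum to 2.4 × 10⁻¹¹, but the
effective value quoted alongside them in the source literature is
2.3 × 10⁻¹¹; the package honours the quoted effective value, and both the
network composition and the override are configurable. Units are
standardised to per-molecule cm³ s⁻¹ throughout — it is the only reading
under which $2/(\alpha n_0)$ lands on the microsecond lifetimes actually
observed at 10¹⁶ cm⁻³ densities.

### Integration

`simulate()` uses `deSolve`'s lsoda with relative tolerance 10⁻⁸ and
absolute tolerance 1 cm⁻³ (one molecule per cm³ — far below any physically
meaningful density here). Returned densities are clipped at a floor of 0.
Pulsed sources deposit their per-pulse yield as an instantaneous density
increment at each pulse onset: the discharge current lasts ~2.1 μs against
a 28.6 μs inter-pulse period, so the deposition width is negligible for
the μs-scale decays of interest. Grid points within a relative 10⁻⁹ of an
onset report the post-deposit density. Conservation is testable directly:
`element_totals()` tracks per-element atom counts, which stay constant to
10⁻⁸ relative for closed networks with sources off.

## The lifetime law

Solving the quadratic loss ODE with $n(0) = n_0$ gives

$$n(t) = \frac{n_0}{1 + \alpha n_0 t}, \qquad
  \tau \equiv \frac{2}{\alpha n_0},$$

so the lifetime is *inversely* proportional to the initial density, and
$n(\tau) = n_0/3$ exactly. For the three depth-resolved initial densities
this predicts:

```{r}
cmp <- compare_theory_experiment(c(4.2, 1.8, 0.8) * 1e16,
                                 c(3.15, 3.61, 3.92) * 1e-6)
data.frame(n0_1e16 = cmp$n0_cm3 / 1e16,
           theory_us = round(cmp$tau_theory_s * 1e6, 2),
           experimental_us = cmp$tau_experimental_s * 1e6)
```

The theoretical column *falls* with density while the measured lifetimes
*rise* with depth (i.e. fall with density much more slowly). The package
computes and reports both sides; explaining the residual disagreement is
an open scientific question, not something the software should paper over.

### Extracting lifetimes from traces

How the experimental lifetimes were read off the emission traces is not
defined by any convention we could adopt with confidence, so
`fit_lifetime()` offers both defensible readings:

* **e-folding** (default): first time after the peak at which the signal
  reaches peak/e, by linear interpolation. Works for intensity traces in
  arbitrary units, where no absolute scale exists.
* **hyperbolic fit**: Levenberg–Marquardt fit of $s_0/(1+\beta t)$ to the
  post-peak segment (seeded from the e-folding estimate), with
  $\tau = 2/\beta$; when the signal is an absolute density this also
  recovers $n_0 = s_0$ and $\alpha = \beta/s_0$.

The fit window opens at the global maximum (signals peak ~100 ns after
discharge onset) with a configurable offset. Note the two conventions
measure different things on a hyperbola: its e-folding time is
$(e-1)/(\alpha n_0) \approx 0.86\,\tau$.

## Beer–Lambert density inversion

The absolute OH• density comes from UV absorption at 309 nm:

$$\frac{I_V}{I_0} = e^{-N\sigma x} \quad\Longleftrightarrow\quad
  N = \frac{\ln(I_0/I_V)}{\sigma x},$$

with defaults $\sigma = 0.6\times10^{-16}\ \mathrm{cm^2}$ (the effective
OH cross-section at 309 nm, treated as a constant — no temperature or
lineshape model is attached to it) and $x = 1$ cm (the 10 mm probe-beam
crossing). The inverse is computed as `log1p((I0-IV)/IV)` rather than a
plain logarithm: in the weak-absorption limit $I_V \to I_0$ the plain log
loses about four significant digits, while the `log1p` form keeps the
forward/inverse pair exact to better than 10⁻¹² relative across
densities from 10¹² to 10¹⁸ cm⁻³. Measurements with $I_V > I_0$
(gain/baseline faults) or $I_V = 0$ (opaque/saturated) are rejected at
construction.

Photon energies use $E = hc/\lambda$ with $hc = 1239.8419$ eV nm (CODATA,
8 significant digits). At 220 nm this gives 5.64 eV — the "~6 eV" often
quoted for the short-wavelength edge is a rounding, and the function
returns the physical value.

### Depth attenuation

The depth decline of the density is modelled as a single exponential
$N(z) = G_0 e^{-\mu z}$ — the simplest monotone model; no functional form
is established for this decline, and the log-domain residual RMS is
reported so lack of fit is visible. The fit is an ordinary least-squares
line in $(z, \ln N)$; depths are stored in mm (the bench convention) and
$\mu$ reported in cm⁻¹:

```{r}
fit_attenuation(depth_profile(c(2, 4, 6), c(4.2e16, 1.3e16, 0.8e16), "DI"))
```

Emission-line assignment matches strict local maxima against a built-in
table (NO γ bands at 224/226/280 nm, the superoxide band at 245 nm, H₂O₂
at 254 nm, OH A–X at 309 nm, O I at 777 nm, O₂ first positive at 852 nm)
within a ±2 nm default tolerance, a deliberate round number for CCD
spectrometers of unstated resolution.

## Cell-level dose

Plasma treatment oxidises the membrane of adherent cells (the
secondary-electron-emission coefficient γ = (I_t − I_i)/I_i measured by a
low-energy He⁺ beam rises from 0.05 to 0.12 after 60 s of treatment) and
shifts the mean molecular surface energy by ~250 meV. Across a
d = 7 nm membrane that shift implies a field

$$E = \Delta V / d \approx 35.7\ \mathrm{MV/m},$$

and an electrostatic stress $\tfrac12 K \varepsilon_0 E^2$ with K = 5.8
and $\varepsilon_0 = 8.8541878\times10^{-12}$ F/m. Evaluating that formula
at these constants gives ~31–33 kPa; the ~2 kPa sometimes quoted for this
configuration is not reproducible from the formula and its own constants,
and `electric_stress()` returns the formula's value — the discrepancy is
documented rather than reconciled by altering constants.

### The nT criterion

The proposed apoptosis threshold is a dose: density × effective exposure
time. "Effective" needs a convention, because OH• exists only
transiently after each discharge pulse. The package's default is the
**duty-cycled** reading

$$T = t_{\mathrm{exposure}} \times f \times \tau,$$

e.g. 60 s × 35 kHz × 3.15 μs ≈ 6.6 s: of a one-minute treatment, the cell
actually sees radicals for about seven seconds. This is the only reading
that brings $nT$ to the 10¹⁶ cm⁻³ s order of the published threshold
(~2.9 × 10¹⁶ cm⁻³ s); taking $T$ as the raw 60 s is selectable
(`convention = "exposure"`) and the convention used is recorded in every
dose report. The arithmetic connecting the two published thresholds
(density 0.3 × 10¹⁶ cm⁻³ at 60 s, dose 2.9 × 10¹⁶ cm⁻³ s) implies an
effective time of ~9.7 s whose derivation is not stated; because their
mutual consistency is unresolved, `dose_criterion()` evaluates **both**
sub-criteria — dose ≥ threshold, or density ≥ threshold under ≥ 60 s
treatment — reports them separately, and flags apoptosis if either holds:

```{r}
T_eff <- effective_exposure_time(60, 35000, 3.15e-6)
das <- dose_criterion(c(1.9e16, 0.5e16, 0.13e16), T_eff, exposure = 60)
data.frame(depth_mm = c(2, 4, 6), n = das$n, nT = das$dose_nT,
           dose_met = das$dose_met, density_met = das$density_met,
           apoptotic = das$apoptotic)
```

This reproduces the observed depth dependence: apoptosis at 2 and 4 mm,
none at 6 mm.

Discharge power is the trapezoidal integral of $V(t)I(t)$ over one period
divided by the period. Reconstructing the drive as a bipolar square wave —
|V| = 1 kV and |I| = 34 mA during two 2.1 μs pulses per 28.6 μs period,
with $VI > 0$ in both half-cycles — gives 5.0 W (a unipolar reading gives
2.5 W); the waveform shape is known only graphically, so the package
integrates whatever sampled waveform it is given.

## The synthetic-data generators

No instrument data ships with the package; `make_decay_trace()`,
`make_pulse_train()`, `make_depth_dataset()`, `make_depth_profile()` and
`make_ph_current_series()` generate the fixtures the estimators are
validated against, under the study's own conditions: peak densities of
order 10¹⁶ cm⁻³, a 100 ns linear rise to peak, 35 kHz pulse repetition,
and multiplicative Gaussian noise with relative σ = 0.05 — the ±5% error
band quoted for the density measurements, used as a proxy for
photodetector gain noise. The pH–current generator assumes the
photodetachment current is linear in [OH⁻] (a decade per pH unit); the
true functional relation is known only graphically and the assumption is
recorded in the output metadata.

Every generator embeds its full ground truth in the output metadata, and
each draws from a random stream derived from the master seed and its own
label (`derive_seed()`, a 31-bit hash), so adding a generator never
perturbs existing fixtures and identical configurations yield
byte-identical CSVs.

**What passing tests do and do not show.** The generators emulate ideal
hyperbolic decays, clean exponential attenuation and exactly
multiplicative noise. Real traces carry baseline drift, afterglow
contamination from neighbouring emission lines, detector nonlinearity and
depth-dependent scattering that these generators deliberately omit —
recovery results here validate the estimators' correctness, not the
instrument chain.

## Numerical choices and degenerate inputs

* Integrator: lsoda, rtol 10⁻⁸, atol 1 cm⁻³; density floor 0; integrator
  failure reports the last successful time.
* Hyperbolic fits are seeded from the e-folding crossing and refuse
  nonpositive decay rates; traces that never reach peak/e advise a longer
  recording.
* `fit_attenuation()` refuses nonpositive densities by naming the
  offending depth; two-point profiles are fit exactly.
* Zero-density states, zero sources and α = 0 all propagate exactly
  (no-loss limits are preserved, not approximated).
* Config validation reports block-indexed locations
  (`reactions[2]: missing 'k'`); the YAML reader does not expose source
  line numbers, a known limitation.
* Validation problem sizes: oracle comparisons use 200–400 point grids
  over ten lifetimes; recovery studies use 20 replicates of ~1000-sample
  traces — comfortable for a laptop R session and far denser than the
  underlying 3-point experimental profiles.

## Known limitations

* The kinetic network is zero-dimensional: no diffusion or spatial
  transport (the modelled regime assumes diffusive loss is small over a
  radical lifetime), and no gas-phase discharge physics.
* The default chemistry is only as complete as the textually reported
  channels; users with a fuller mechanism should supply it via the config
  format.
* The depth-attenuation model is single-exponential by choice; real
  profiles mixing absorption and scattering may need more structure.
* The theory/experiment lifetime discrepancy is reported, not explained.
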