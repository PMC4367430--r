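# Seeded synthetic-data generators: instrument-like fixtures with known
# ground truth. Noise is multiplicative Gaussian (relative sigma, default
# 0.05, matching the +/-5% error band quoted for the density measurements);
# at sigma = 0 every generator is an exact evaluation of its closed form.
#
# Each generator draws from a stream derived deterministically from the
# master seed and its own label, so adding a generator never perturbs the
# fixtures of existing ones.

#' Configuration for the synthetic-data generators
#'
#' @param seed Master integer seed; per-generator streams are derived from
#'   it.
#' @param sigma Relative standard deviation of the multiplicative Gaussian
#'   noise (default 0.05).
#' @param sampling_interval Sample spacing, s (default 20 ns).
#' @param duration Trace duration, s (default 20 us).
#' @param ground_truth Free-form list echoed into output metadata.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, sigma = 0.05,
                             sampling_interval = 2e-8, duration = 2e-5,
                             ground_truth = list()) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sampling_interval <= 0)
    stop("sampling_interval must be > 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), sigma = sigma,
         sampling_interval = sampling_interval, duration = duration,
         ground_truth = ground_truth),
    class = "synthetic_config"
  )
}

#' Derive a generator-specific seed from the master seed
#'
#' Deterministic 31-bit hash of (seed, label); keeps derived seeds valid R
#' integers.
#'
#' @param seed Master integer seed.
#' @param label Generator label.
#' @return Integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(seed) %% m) * 1000003 %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

mult_noise <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else 1 + rnorm(n, sd = sigma)
}

#' Generate a synthetic OH decay trace
#'
#' A 100 ns linear rise to the peak density (emulating the build-up after
#' discharge onset) followed by the quadratic-loss decay
#' `n0 / (1 + alpha*n0*t)`, with multiplicative Gaussian noise.
#'
#' @param n0 Peak density, cm^-3.
#' @param alpha Recombination coefficient, cm^3 s^-1.
#' @param cfg A [synthetic_config()].
#' @param rise_time Rise duration before the peak, s (default 100 ns).
#' @return A [decay_trace()]; `metadata$ground_truth` holds `n0`, `alpha`,
#'   `tau`, `rise_time`, `sigma` and `seed`.
#' @export
#' @examples
#' tr <- make_decay_trace(4.2e16, 2.3e-11, synthetic_config(seed = 7))
#' fit_lifetime(tr, "hyperbolic_fit")
make_decay_trace <- function(n0, alpha, cfg = synthetic_config(),
                             rise_time = 1e-7) {
  times <- seq(0, cfg$duration, by = cfg$sampling_interval)
  clean <- ifelse(times < rise_time,
                  n0 * times / rise_time,
                  analytic_decay(n0, alpha, pmax(times - rise_time, 0)))
  set.seed(derive_seed(cfg$seed, "decay_trace"))
  signal <- clean * mult_noise(length(clean), cfg$sigma)
  decay_trace(
    times, signal,
    metadata = list(ground_truth = list(
      n0 = n0, alpha = alpha, tau = predicted_lifetime(n0, alpha),
      rise_time = rise_time, sigma = cfg$sigma, seed = cfg$seed))
  )
}

#' Generate a pulsed-discharge density trace
#'
#' Each pulse deposits `per_pulse_n0` instantaneously at onset; between
#' pulses the density follows the exact quadratic-loss solution from
#' whatever residual density remains. With `n_pulses = 1` this reduces to a
#' single decay with no rise ramp.
#'
#' @param per_pulse_n0 Per-pulse density increment, cm^-3.
#' @param alpha Recombination coefficient, cm^3 s^-1.
#' @param f Pulse repetition frequency, Hz (default 35 kHz).
#' @param n_pulses Number of pulses (>= 1).
#' @param cfg A [synthetic_config()]; the trace covers `n_pulses` periods
#'   at `cfg$sampling_interval`.
#' @return A [decay_trace()] with pulse onset times in
#'   `metadata$pulse_onsets`.
#' @export
make_pulse_train <- function(per_pulse_n0, alpha, f = 35000, n_pulses,
                             cfg = synthetic_config()) {
  if (f <= 0) stop("repetition frequency must be > 0", call. = FALSE)
  if (n_pulses < 1) stop("need at least one pulse", call. = FALSE)
  period <- 1 / f
  times <- seq(0, n_pulses * period, by = cfg$sampling_interval)
  onsets <- (seq_len(n_pulses) - 1) * period
  clean <- numeric(length(times))
  for (j in seq_len(n_pulses)) {
    t_on <- onsets[j]
    t_off <- if (j < n_pulses) onsets[j + 1] else times[length(times)]
    residual <- if (j == 1) 0 else
      analytic_decay(n_start, alpha, period)
    n_start <- residual + per_pulse_n0
    seg <- times >= t_on - 1e-15 & times <= t_off + 1e-15
    clean[seg] <- analytic_decay(n_start, alpha, times[seg] - t_on)
  }
  set.seed(derive_seed(cfg$seed, "pulse_train"))
  signal <- clean * mult_noise(length(clean), cfg$sigma)
  decay_trace(
    times, signal,
    metadata = list(
      pulse_onsets = onsets,
      ground_truth = list(per_pulse_n0 = per_pulse_n0, alpha = alpha,
                          f = f, n_pulses = n_pulses, sigma = cfg$sigma,
                          seed = cfg$seed))
  )
}

#' Generate a synthetic depth-resolved absorption dataset
#'
#' The true density declines exponentially with depth,
#' `N(z) = G0 * exp(-mu * z)`; transmitted intensities follow Beer-Lambert
#' with multiplicative noise. Inverting the noiseless output reproduces the
#' truth exactly.
#'
#' @param G0 Surface density scale, cm^-3.
#' @param mu Attenuation coefficient, cm^-1.
#' @param depths_mm Measurement depths, mm.
#' @param sigma_cm2 Absorption cross-section, cm^2.
#' @param path_cm Absorption path, cm.
#' @param I0 Incident intensity, arbitrary units.
#' @param cfg A [synthetic_config()].
#' @param solution Solution label for the ground-truth profile.
#' @return List with `measurements` (data.frame: `depth_mm`, `wavelength_nm`,
#'   `I0`, `IV`, `path_cm`, `sigma_cm2`) and `truth` (a [depth_profile()]).
#' @export
make_depth_dataset <- function(G0, mu, depths_mm,
                               sigma_cm2 = ohkin_constants$sigma_oh_309nm,
                               path_cm = 1, I0 = 1,
                               cfg = synthetic_config(),
                               solution = "DI") {
  if (length(depths_mm) == 0) stop("depths must be nonempty", call. = FALSE)
  if (G0 < 0 || mu < 0) stop("G0 and mu must be >= 0", call. = FALSE)
  N_true <- G0 * exp(-mu * depths_mm / 10)
  set.seed(derive_seed(cfg$seed, "depth_dataset"))
  IV <- I0 * transmission_from_density(N_true, sigma_cm2, path_cm) *
    mult_noise(length(N_true), cfg$sigma)
  list(
    measurements = data.frame(
      depth_mm = depths_mm, wavelength_nm = 309, I0 = I0, IV = IV,
      path_cm = path_cm, sigma_cm2 = sigma_cm2),
    truth = depth_profile(depths_mm, N_true, solution)
  )
}

#' Generate a noisy depth profile of densities
#'
#' Emulates the depth-resolved density measurement directly: the true
#' exponential decline `N(z) = G0 * exp(-mu * z)` with multiplicative
#' Gaussian noise on the densities themselves (the measurement's quoted
#' error band is a relative one).
#'
#' @param G0 Surface density scale, cm^-3.
#' @param mu Attenuation coefficient, cm^-1.
#' @param depths_mm Measurement depths, mm.
#' @param cfg A [synthetic_config()].
#' @param solution Solution label.
#' @return A [depth_profile()]; ground truth in attribute `ground_truth`.
#' @export
make_depth_profile <- function(G0, mu, depths_mm,
                               cfg = synthetic_config(),
                               solution = "DI") {
  if (length(depths_mm) == 0) stop("depths must be nonempty", call. = FALSE)
  if (G0 < 0 || mu < 0) stop("G0 and mu must be >= 0", call. = FALSE)
  N_true <- G0 * exp(-mu * depths_mm / 10)
  set.seed(derive_seed(cfg$seed, "depth_profile"))
  prof <- depth_profile(depths_mm,
                        pmax(N_true * mult_noise(length(N_true), cfg$sigma),
                             0),
                        solution)
  attr(prof, "ground_truth") <- list(G0 = G0, mu = mu, sigma = cfg$sigma,
                                     seed = cfg$seed)
  prof
}

#' Generate a pH series of photodetachment currents
#'
#' Emulates the submerged-electrode current measurement: the current is
#' proportional to the hydroxide photodetachment rate, hence linear in
#' \[OH-\] and strongly increasing with pH (a decade per pH unit).
#'
#' @param ph_values pH values in \[0, 14\].
#' @param gain Current per unit volumetric detachment rate, A/(cm^-3 s^-1).
#' @param cfg A [synthetic_config()].
#' @param photon_energy Photon energy driving detachment, eV (default 4:
#'   the 309 nm band).
#' @param photon_flux Photon flux, cm^-2 s^-1.
#' @param cross_section Detachment cross-section, cm^2.
#' @return data.frame with `ph`, `oh_minus_cm3`, `current_A`; ground truth
#'   in attribute `ground_truth`.
#' @export
make_ph_current_series <- function(ph_values, gain = 1e-15,
                                   cfg = synthetic_config(),
                                   photon_energy = 4, photon_flux = 1e16,
                                   cross_section = 1e-18) {
  dens <- hydroxide_density_from_ph(ph_values)
  rate <- photodetachment_source(dens, photon_energy, photon_flux,
                                 cross_section)
  set.seed(derive_seed(cfg$seed, "ph_current"))
  current <- gain * rate * mult_noise(length(rate), cfg$sigma)
  out <- data.frame(ph = ph_values, oh_minus_cm3 = dens,
                    current_A = current)
  attr(out, "ground_truth") <- list(
    gain = gain, photon_energy = photon_energy, photon_flux = photon_flux,
    cross_section = cross_section, sigma = cfg$sigma, seed = cfg$seed,
    model = "current linear in [OH-]")
  out
}
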