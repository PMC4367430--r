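# Membrane electrostatics, secondary electron emission, discharge power and
# the nT apoptosis dose criterion.

#' Transmembrane electric field
#'
#' `E = delta_v / d`. With the plasma-induced 250 meV surface-energy shift
#' across a 7 nm membrane this yields ~35 MV/m, enough to distort the
#' membrane of an adherent cell.
#'
#' @param delta_v Transmembrane potential shift, V.
#' @param d_m Membrane thickness, m (default 7e-9).
#' @return Field, V m^-1.
#' @export
#' @examples
#' membrane_field(0.25) / 1e6   # ~35.7 MV/m
membrane_field <- function(delta_v, d_m = 7e-9) {
  if (d_m <= 0) stop("membrane thickness must be > 0", call. = FALSE)
  delta_v / d_m
}

#' Electrostatic stress on a dielectric membrane
#'
#' `stress = 1/2 * K * epsilon0 * E^2` (Maxwell stress in a dielectric of
#' relative permittivity K).
#'
#' @param E Electric field, V m^-1 (>= 0).
#' @param K Relative dielectric constant (>= 1; default 5.8 for the cell
#'   membrane).
#' @param epsilon0 Vacuum permittivity, F m^-1.
#' @return Stress, Pa.
#' @export
#' @examples
#' electric_stress(membrane_field(0.25), K = 5.8) / 1e3   # ~32.8 kPa
electric_stress <- function(E, K = 5.8,
                            epsilon0 = ohkin_constants$epsilon0) {
  if (any(E < 0)) stop("field must be >= 0", call. = FALSE)
  if (K < 1) stop("relative dielectric constant must be >= 1", call. = FALSE)
  0.5 * K * epsilon0 * E^2
}

#' Ion-induced secondary electron emission coefficient
#'
#' `gamma = (I_t - I_i) / I_i`, from the two current readings of a
#' low-energy ion-beam probe: `I_i` with secondaries suppressed (ion current
#' only) and `I_t` with secondaries collected.
#'
#' @param I_t Total current (ion + secondary electrons), A.
#' @param I_i Ion current, A (> 0).
#' @return Dimensionless emission coefficient.
#' @export
#' @examples
#' gamma_coefficient(1.12e-9, 1e-9)   # 0.12: oxidised membrane
#' gamma_coefficient(1.05e-9, 1e-9)   # 0.05: control
gamma_coefficient <- function(I_t, I_i) {
  if (any(I_i <= 0)) stop("ion current must be > 0", call. = FALSE)
  (I_t - I_i) / I_i
}

#' Construct a discharge waveform
#'
#' @param times Increasing sample times, s; must span at least one period.
#' @param voltage Voltage samples, V.
#' @param current Current samples, A.
#' @param period Pulse period, s (default 1/35000).
#' @return An object of class `discharge_waveform`.
#' @export
discharge_waveform <- function(times, voltage, current,
                               period = 1 / 35000) {
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(voltage) != length(times) || length(current) != length(times))
    stop("voltage/current must match times in length", call. = FALSE)
  if (times[length(times)] - times[1] < period * (1 - 1e-9))
    stop("waveform must span at least one full period", call. = FALSE)
  structure(
    list(times = times, voltage = voltage, current = current,
         period = period),
    class = "discharge_waveform"
  )
}

#' Mean discharge power over one period
#'
#' `P = (1/T) * integral of V(t)*I(t) dt` over one period, by trapezoidal
#' integration of the sampled waveform. The endpoint at `t0 + T` is
#' linearly interpolated when it falls between samples.
#'
#' @param w A [discharge_waveform()].
#' @return Power, W.
#' @export
#' @examples
#' tt <- seq(0, 1/35000, length.out = 2000)
#' w <- discharge_waveform(tt, rep(10, 2000), rep(0.5, 2000))
#' discharge_power(w)   # 5 W (DC)
discharge_power <- function(w) {
  t_end <- w$times[1] + w$period
  p <- w$voltage * w$current
  sel <- w$times <= t_end
  tt <- w$times[sel]
  pp <- p[sel]
  if (tt[length(tt)] < t_end) {
    p_end <- approx(w$times, p, xout = t_end)$y
    tt <- c(tt, t_end)
    pp <- c(pp, p_end)
  }
  n <- length(tt)
  sum(diff(tt) * (pp[-1] + pp[-n]) / 2) / w$period
}

#' Effective radical exposure time
#'
#' With pulsed generation at repetition frequency `f`, radicals exist only
#' during their post-pulse lifetime `tau`, so over a plasma treatment of
#' duration `exposure` the cell actually sees radicals for
#' `T = exposure * f * tau` (the duty-cycled convention, default). The
#' alternative `"exposure"` convention takes the full treatment time.
#'
#' @param exposure Plasma treatment duration, s.
#' @param f Pulse repetition frequency, Hz.
#' @param tau Per-pulse radical lifetime, s.
#' @param convention `"duty"` (default) or `"exposure"`.
#' @return Effective time, s, with attribute `convention`.
#' @export
#' @examples
#' effective_exposure_time(60, 35000, 3.92e-6)   # ~8.23 s
effective_exposure_time <- function(exposure, f, tau,
                                    convention = c("duty", "exposure")) {
  convention <- match.arg(convention)
  if (any(c(exposure, f, tau) < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  T_eff <- if (convention == "duty") exposure * f * tau else exposure
  attr(T_eff, "convention") <- convention
  T_eff
}

#' Assess the nT apoptosis dose criterion
#'
#' The dose metric is `nT`: OH density times effective exposure time.
#' A treatment is classified apoptotic when either sub-criterion holds:
#' the dose reaches `threshold_dose`, or the density reaches
#' `threshold_density` under a treatment of at least 60 s. Both
#' sub-criteria are reported separately because the two published
#' thresholds are stated independently.
#'
#' @param n OH density at the cell, cm^-3.
#' @param T_eff Effective exposure time, s (see
#'   [effective_exposure_time()]).
#' @param threshold_dose Dose threshold, cm^-3 s (default 2.9e16).
#' @param threshold_density Density threshold at 60 s exposure, cm^-3
#'   (default 0.3e16).
#' @param exposure Treatment duration, s (used by the density sub-criterion).
#' @return A `dose_assessment`: list with `n`, `T_eff`, `dose_nT`,
#'   `dose_met`, `density_met`, `apoptotic`, thresholds and the effective
#'   time convention if `T_eff` carries one.
#' @export
#' @examples
#' dose_criterion(1.9e16, effective_exposure_time(60, 35000, 3.15e-6),
#'                exposure = 60)$apoptotic   # TRUE at 2 mm
#' dose_criterion(0.13e16, effective_exposure_time(60, 35000, 3.92e-6),
#'                exposure = 60)$apoptotic   # FALSE at 6 mm
dose_criterion <- function(n, T_eff, threshold_dose = 2.9e16,
                           threshold_density = 0.3e16, exposure = 60) {
  if (any(c(n, T_eff, threshold_dose, threshold_density, exposure) < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  dose <- n * as.numeric(T_eff)
  dose_met <- dose >= threshold_dose
  density_met <- n >= threshold_density & exposure >= 60
  structure(
    list(n = n, T_eff = as.numeric(T_eff), dose_nT = dose,
         dose_met = dose_met, density_met = density_met,
         apoptotic = dose_met | density_met,
         threshold_dose = threshold_dose,
         threshold_density = threshold_density,
         exposure = exposure,
         convention = attr(T_eff, "convention") %||% "unspecified"),
    class = "dose_assessment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dose_assessment <- function(x, ...) {
  cat(sprintf(
    "<dose_assessment: n = %.3g cm^-3, T = %.3g s, nT = %.3g cm^-3 s,\n",
    x$n[1], x$T_eff[1], x$dose_nT[1]))
  cat(sprintf("  dose_met = %s, density_met = %s -> apoptotic = %s (%s)>\n",
              paste(x$dose_met, collapse = ","),
              paste(x$density_met, collapse = ","),
              paste(x$apoptotic, collapse = ","), x$convention))
  invisible(x)
}
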