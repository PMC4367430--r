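# UV absorption spectroscopy: Beer-Lambert forward/inverse, photon energy,
# emission-line assignment, depth-attenuation fitting.

#' Construct an absorption measurement
#'
#' @param I0 Incident intensity, arbitrary units (> 0).
#' @param IV Transmitted intensity, same units (> 0, <= I0).
#' @param path_cm Absorption path length, cm (default 1.0: the 10 mm probe
#'   beam crossing of the cuvette).
#' @param sigma_cm2 Effective absorption cross-section, cm^2 (default
#'   0.6e-16 for OH at 309 nm).
#' @param wavelength_nm Probe wavelength, nm.
#' @return An object of class `absorption_measurement`.
#' @export
absorption_measurement <- function(I0, IV, path_cm = 1,
                                   sigma_cm2 = ohkin_constants$sigma_oh_309nm,
                                   wavelength_nm = 309) {
  if (I0 <= 0) stop("incident intensity must be > 0", call. = FALSE)
  if (IV <= 0)
    stop("transmitted intensity must be > 0 (opaque or saturated sample)",
         call. = FALSE)
  if (IV > I0)
    stop("transmitted intensity exceeds incident intensity; ",
         "check gain/baseline", call. = FALSE)
  if (path_cm <= 0 || sigma_cm2 <= 0)
    stop("path_cm and sigma_cm2 must be > 0", call. = FALSE)
  structure(
    list(I0 = I0, IV = IV, path_cm = path_cm, sigma_cm2 = sigma_cm2,
         wavelength_nm = wavelength_nm),
    class = "absorption_measurement"
  )
}

#' Absorber density from a Beer-Lambert measurement
#'
#' Inverts `IV/I0 = exp(-N*sigma*x)`:  `N = ln(I0/IV) / (sigma * x)`.
#'
#' @param m An [absorption_measurement()].
#' @return Density N, cm^-3.
#' @export
#' @examples
#' m <- absorption_measurement(I0 = 1, IV = exp(-1), path_cm = 1,
#'                             sigma_cm2 = 0.6e-16)
#' density_from_absorption(m)   # 1/(sigma*x) = 1.667e16
density_from_absorption <- function(m) {
  stopifnot(inherits(m, "absorption_measurement"))
  # log1p((I0-IV)/IV) = ln(I0/IV) but keeps full precision in the
  # weak-absorption limit IV -> I0, where plain log loses ~4 digits
  log1p((m$I0 - m$IV) / m$IV) / (m$sigma_cm2 * m$path_cm)
}

#' Transmitted fraction from an absorber density
#'
#' Forward Beer-Lambert law: `IV/I0 = exp(-N*sigma*x)`, in (0, 1].
#'
#' @param N Absorber density, cm^-3 (>= 0).
#' @param sigma_cm2 Cross-section, cm^2 (>= 0).
#' @param path_cm Path length, cm (>= 0).
#' @return Dimensionless transmitted fraction.
#' @export
#' @examples
#' transmission_from_density(4.2e16, 0.6e-16, 1)   # exp(-2.52) ~ 0.0805
transmission_from_density <- function(N,
                                      sigma_cm2 = ohkin_constants$sigma_oh_309nm,
                                      path_cm = 1) {
  if (any(N < 0) || any(sigma_cm2 < 0) || any(path_cm < 0))
    stop("N, sigma_cm2 and path_cm must be >= 0", call. = FALSE)
  exp(-N * sigma_cm2 * path_cm)
}

#' Photon energy from wavelength
#'
#' `E = hc / lambda` with `hc = 1239.8419 eV nm`.
#'
#' @param wavelength_nm Wavelength, nm (> 0); vectorised.
#' @return Photon energy, eV.
#' @export
#' @examples
#' photon_energy(309)   # 4.01 eV: the OH emission band
#' photon_energy(220)   # 5.64 eV (often quoted rounded up to ~6 eV)
photon_energy <- function(wavelength_nm) {
  if (any(wavelength_nm <= 0))
    stop("wavelength must be > 0", call. = FALSE)
  ohkin_constants$hc_eV_nm / wavelength_nm
}

# Reference emission lines of the plasma-liquid system (nm -> species).
emission_line_table <- data.frame(
  wavelength_nm = c(224, 226, 245, 254, 280, 309, 777, 852),
  species = c("NO", "NO", "O2*-", "H2O2", "NO", "OH", "O I",
              "O2 first positive"),
  transition = c("NO gamma", "NO gamma", "superoxide band",
                 "H2O2 absorption band", "NO gamma",
                 "OH A-X (0,0)", "OI 5S0-5P", "O2 b-X"),
  stringsAsFactors = FALSE
)

#' Assign emission-line peaks to species
#'
#' Strict local maxima of the spectrum are matched against a built-in table
#' of plasma-liquid emission lines (NO gamma bands, the superoxide band,
#' H2O2, OH A-X at 309 nm, atomic oxygen at 777 nm, O2 first positive at
#' 852 nm). Peaks farther than `tolerance_nm` from every table entry are
#' labelled `"unassigned"`.
#'
#' @param wavelengths_nm Increasing wavelength grid, nm.
#' @param intensities Intensities on the grid, arbitrary units.
#' @param tolerance_nm Matching tolerance, nm (default 2).
#' @return data.frame with `wavelength_nm`, `intensity`, `species`,
#'   `transition`; zero rows for a spectrum with no local maxima.
#' @export
assign_lines <- function(wavelengths_nm, intensities, tolerance_nm = 2) {
  if (tolerance_nm <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be increasing", call. = FALSE)
  n <- length(intensities)
  if (n < 3)
    return(data.frame(wavelength_nm = numeric(0), intensity = numeric(0),
                      species = character(0), transition = character(0)))
  i <- 2:(n - 1)
  is_peak <- intensities[i] > intensities[i - 1] &
    intensities[i] > intensities[i + 1]
  idx <- i[is_peak]
  out <- lapply(idx, function(j) {
    d <- abs(emission_line_table$wavelength_nm - wavelengths_nm[j])
    m <- which.min(d)
    if (d[m] <= tolerance_nm)
      data.frame(wavelength_nm = wavelengths_nm[j],
                 intensity = intensities[j],
                 species = emission_line_table$species[m],
                 transition = emission_line_table$transition[m],
                 stringsAsFactors = FALSE)
    else
      data.frame(wavelength_nm = wavelengths_nm[j],
                 intensity = intensities[j],
                 species = "unassigned", transition = "",
                 stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(wavelength_nm = numeric(0), intensity = numeric(0),
                      species = character(0), transition = character(0)))
  do.call(rbind, out)
}

#' Construct a depth profile
#'
#' @param depth_mm Strictly increasing depths below the surface, mm.
#' @param density_cm3 Densities at each depth, cm^-3 (>= 0).
#' @param solution One of `"DI"`, `"PBS"`, `"other"`.
#' @return An object of class `depth_profile` (a data.frame).
#' @export
depth_profile <- function(depth_mm, density_cm3,
                          solution = c("DI", "PBS", "other")) {
  solution <- match.arg(solution)
  if (any(diff(depth_mm) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (any(density_cm3 < 0))
    stop("densities must be >= 0", call. = FALSE)
  structure(
    data.frame(depth_mm = depth_mm, density_cm3 = density_cm3,
               solution = solution),
    class = c("depth_profile", "data.frame")
  )
}

#' Fit an exponential attenuation model to a depth profile
#'
#' Models the depth decline of the UV-driven OH density as
#' `N(z) = G0 * exp(-mu * z)` and fits it as a least-squares line in
#' `(depth, ln density)`. Depths are stored in mm but the attenuation
#' coefficient is reported in cm^-1.
#'
#' @param profile A [depth_profile()] with >= 2 entries, all densities > 0.
#' @return An `attenuation_model`: list with `G0` (cm^-3), `mu` (cm^-1) and
#'   `residual_rms` (log domain).
#' @export
#' @examples
#' p <- depth_profile(c(2, 4, 6), c(4.2e16, 1.3e16, 0.8e16), "DI")
#' fit_attenuation(p)$mu    # ~4.15 cm^-1
fit_attenuation <- function(profile) {
  if (nrow(profile) < 2)
    stop("need at least 2 depth entries", call. = FALSE)
  bad <- profile$density_cm3 <= 0
  if (any(bad))
    stop("nonpositive density at depth ",
         paste(profile$depth_mm[bad], collapse = ", "), " mm",
         call. = FALSE)
  depth_cm <- profile$depth_mm / 10
  fit <- lm(log(profile$density_cm3) ~ depth_cm)
  co <- coef(fit)
  structure(
    list(G0 = exp(co[[1]]), mu = -co[[2]],
         residual_rms = sqrt(mean(resid(fit)^2))),
    class = "attenuation_model"
  )
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model: G0 = %.3g cm^-3, mu = %.3g cm^-1, ",
              x$G0, x$mu),
      sprintf("log-rms = %.3g>\n", x$residual_rms), sep = "")
  invisible(x)
}
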