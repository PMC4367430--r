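# Kinetic integration of the reaction network.
#
# Rate convention ("density-loss"): for a reaction with event rate
# R = k * prod(n_j^s_j), the lead reactant (the one with the largest
# stoichiometry s_max) loses density at exactly k * prod(n^s), i.e. the
# per-event consumption factor is absorbed into k. This is the convention
# under which the quadratic OH loss reads dn/dt = -alpha*n^2 and the
# lifetime law tau = 2/(alpha*n0) reproduces the reported theory column.
# Concretely each species i changes by (p_i - s_i) * R / s_max, which
# conserves atoms exactly because (p_i - s_i) is balanced.

#' Instantaneous rate of change of all species densities
#'
#' @param state An [kinetic_state()] (or named density vector); may include
#'   only a subset of network species, the rest are taken as zero except for
#'   background species which are held at their configured density.
#' @param network An `ohkin_network`.
#' @param source Optional [source_term()]; a continuous source adds its
#'   amplitude to the target's derivative (pulsed sources act as density
#'   increments in [simulate()], not as derivatives).
#' @return Named numeric vector of dn/dt, cm^-3 s^-1, for every network
#'   species; background species report 0.
#' @export
#' @examples
#' net <- oh_recombination_network(alpha = 2.3e-11)
#' st <- kinetic_state(0, c(OH = 1e16, H2O2 = 0))
#' rate_of_change(st, net)[["OH"]]   # -2.3e21
rate_of_change <- function(state, network, source = NULL) {
  dens <- if (inherits(state, "ohkin_state")) state$densities else state
  all_names <- names(network$species)
  unknown <- setdiff(names(dens), all_names)
  if (length(unknown) > 0)
    stop("unknown species in state: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- setNames(numeric(length(all_names)), all_names)
  n[names(dens)] <- dens
  bg <- network$background_densities
  if (length(bg) > 0) n[names(bg)] <- bg
  dn <- setNames(numeric(length(all_names)), all_names)
  for (r in network$reactions) {
    rate <- r$k * prod(n[names(r$reactants)]^r$reactants)
    if (rate == 0) next
    ev <- rate / max(r$reactants)      # event rate under density-loss convention
    dn[names(r$reactants)] <- dn[names(r$reactants)] - r$reactants * ev
    dn[names(r$products)] <- dn[names(r$products)] + r$products * ev
  }
  if (!is.null(source) && source$mode == "continuous")
    dn[source$target] <- dn[source$target] + source$amplitude
  if (length(bg) > 0) dn[names(bg)] <- 0
  dn
}

#' Integrate a reaction network on a time grid
#'
#' Stiff implicit integration (lsoda) with relative tolerance 1e-8 and
#' absolute tolerance 1 cm^-3; densities are clipped at a floor of 0 in the
#' returned trajectory. Pulsed sources deposit their per-pulse yield as an
#' instantaneous density increment at each pulse onset.
#'
#' @param network An `ohkin_network`.
#' @param initial An [kinetic_state()] with the initial densities.
#' @param source Optional [source_term()].
#' @param t_grid Strictly increasing vector of output times, s; the first
#'   entry is the initial time.
#' @param solver_options List overriding `rtol` (1e-8), `atol` (1) and
#'   `method` ("lsoda").
#' @return A data.frame with column `time_s` followed by one density column
#'   per species (cm^-3), class `ohkin_trajectory`.
#' @export
#' @examples
#' net <- oh_recombination_network(2.3e-11)
#' tr <- simulate(net, kinetic_state(0, c(OH = 4.2e16, H2O2 = 0)),
#'                t_grid = seq(0, 2e-5, length.out = 101))
#' max(abs(tr$OH - analytic_decay(4.2e16, 2.3e-11, tr$time_s)) / 4.2e16)
simulate <- function(network, initial, source = NULL, t_grid,
                     solver_options = list()) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  if (any(initial$densities < 0))
    stop("initial densities must be >= 0", call. = FALSE)
  opts <- modifyList(list(rtol = 1e-8, atol = 1, method = "lsoda"),
                     solver_options)
  all_names <- names(network$species)
  y0 <- setNames(numeric(length(all_names)), all_names)
  y0[names(initial$densities)] <- initial$densities
  bg <- network$background_densities
  if (length(bg) > 0) y0[names(bg)] <- bg

  deriv <- function(t, y, parms) {
    list(rate_of_change(setNames(pmax(y, 0), all_names), network,
                        source = if (!is.null(source) &&
                                     source$mode == "continuous") source))
  }
  run_segment <- function(y, times) {
    if (length(times) == 1L)
      return(matrix(c(times, y), nrow = 1,
                    dimnames = list(NULL, c("time", all_names))))
    out <- try(deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
                            method = opts$method, rtol = opts$rtol,
                            atol = opts$atol), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(times)) {
      last_t <- if (inherits(out, "try-error")) times[1]
                else out[nrow(out), "time"]
      stop(sprintf("integrator failed; last successful time %.6g s", last_t),
           call. = FALSE)
    }
    out
  }

  if (!is.null(source) && source$mode == "pulsed") {
    period <- 1 / source$repetition_frequency
    t0 <- t_grid[1]; t1 <- t_grid[length(t_grid)]
    onsets <- seq(t0, t1, by = period)
    tiny <- period * 1e-9
    # grid points within `tiny` of an onset report the post-deposit density
    seg_of <- findInterval(t_grid + tiny, onsets)
    out <- matrix(NA_real_, length(t_grid), length(all_names) + 1,
                  dimnames = list(NULL, c("time", all_names)))
    out[, "time"] <- t_grid
    y <- y0
    for (j in seq_along(onsets)) {
      y[source$target] <- y[source$target] + source$amplitude
      t_stop <- if (j < length(onsets)) onsets[j + 1] else t1
      idx <- which(seg_of == j)
      inner <- t_grid[idx]
      inner <- inner[inner > onsets[j] + tiny & inner < t_stop - tiny]
      times <- sort(unique(c(onsets[j], inner, t_stop)))
      seg <- run_segment(y, times)
      for (i in idx) {
        k <- which.min(abs(times - t_grid[i]))
        out[i, all_names] <- seg[k, all_names]
      }
      y <- setNames(seg[nrow(seg), all_names], all_names)
    }
  } else {
    out <- run_segment(y0, t_grid)
  }
  df <- as.data.frame(out)
  names(df)[1] <- "time_s"
  df[all_names] <- lapply(df[all_names], function(x) pmax(x, 0))
  class(df) <- c("ohkin_trajectory", "data.frame")
  df
}

#' Per-element atom totals along a trajectory
#'
#' Used to verify conservation for stoichiometrically closed networks with
#' sources off: each element's total atom count should be constant to high
#' relative precision.
#'
#' @param traj An `ohkin_trajectory` from [simulate()].
#' @param network The network that produced it.
#' @return A data.frame with `time_s` and one column per element, atoms cm^-3.
#' @export
element_totals <- function(traj, network) {
  els <- unique(unlist(lapply(network$species,
                              function(s) names(s$composition))))
  out <- data.frame(time_s = traj$time_s)
  for (el in els) {
    tot <- 0
    for (s in network$species) {
      cnt <- if (el %in% names(s$composition)) s$composition[[el]] else 0
      if (cnt > 0) tot <- tot + cnt * traj[[s$name]]
    }
    out[[el]] <- tot
  }
  out
}

# Photodetachment source ---------------------------------------------------

#' Hydroxide ion density from pH
#'
#' Converts pH to an aqueous OH- number density via
#' \[OH-\] = 10^(pH - 14) mol/L and Avogadro's number (per cm^3).
#'
#' @param ph pH in \[0, 14\].
#' @return Density, cm^-3.
#' @export
#' @examples
#' hydroxide_density_from_ph(7)   # 6.022e13 cm^-3
#' hydroxide_density_from_ph(9)   # 6.022e15 cm^-3
hydroxide_density_from_ph <- function(ph) {
  if (any(ph < 0 | ph > 14))
    stop("ph must lie in [0, 14]", call. = FALSE)
  10^(ph - 14) * ohkin_constants$avogadro / 1000
}

#' Hydroxide photodetachment source rate
#'
#' OH- + photon -> OH + e-. The process has a 2.4 eV threshold; below it the
#' source is exactly zero. Above threshold the volumetric rate is
#' flux * cross_section * density, and the OH production rate equals the
#' electron production rate.
#'
#' @param oh_minus_density OH- density, cm^-3.
#' @param photon_energy Photon energy, eV.
#' @param photon_flux Photon flux, cm^-2 s^-1.
#' @param cross_section Detachment cross-section, cm^2.
#' @return Source rate, cm^-3 s^-1.
#' @export
#' @examples
#' photodetachment_source(6.022e15, 4, 1e16, 1e-18)   # 6.022e13
#' photodetachment_source(6.022e15, 2.0, 1e16, 1e-18) # 0: below threshold
photodetachment_source <- function(oh_minus_density, photon_energy,
                                   photon_flux, cross_section) {
  if (any(c(oh_minus_density, photon_energy, photon_flux,
            cross_section) < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  above <- as.numeric(photon_energy >= ohkin_constants$oh_minus_detachment_eV)
  above * photon_flux * cross_section * oh_minus_density
}
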