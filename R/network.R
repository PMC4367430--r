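# Reaction-network data structures: species, reactions, networks, sources.
# Densities are cm^-3, rate coefficients cm^3 s^-1 per reacting pair
# (three-body reactions are folded at fixed third-body density), time s.

#' Define a chemical species
#'
#' @param name Short label, e.g. `"OH"`, `"H2O2"`, `"e-"`. Must be unique
#'   within a network.
#' @param charge Integer number of elementary charges (default 0).
#' @param composition Named integer vector mapping element symbol to atom
#'   count, e.g. `c(H = 1, O = 1)`. Electrons have an empty composition.
#' @return An object of class `ohkin_species`.
#' @export
#' @examples
#' species("OH", 0, c(H = 1, O = 1))
#' species("e-", -1, integer(0))
species <- function(name, charge = 0L, composition = integer(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  composition <- unlist(composition)
  if (length(composition) > 0 && (is.null(names(composition)) ||
                                  any(!nzchar(names(composition)))))
    stop("composition must be a named element -> count vector", call. = FALSE)
  if (any(composition < 0))
    stop("composition counts must be >= 0", call. = FALSE)
  structure(
    list(name = name, charge = as.integer(charge),
         composition = composition),
    class = "ohkin_species"
  )
}

#' Define a reaction
#'
#' Stoichiometries are given as named numeric vectors (species -> count).
#' The rate coefficient `k` is an effective two-body coefficient in
#' cm^3 s^-1; three-body reactions must be folded at a fixed third-body
#' density before entry.
#'
#' @param reactants,products Named numeric vectors, species name -> integer
#'   stoichiometry.
#' @param k Rate coefficient, cm^3 s^-1, must be >= 0.
#' @param label Free-form provenance note.
#' @param photon_driven Logical; photon-driven reactions are exempt from
#'   energy bookkeeping but must still balance atoms and charge.
#' @return An object of class `ohkin_reaction`.
#' @export
#' @examples
#' reaction(c(OH = 2), c(H2O2 = 1), k = 1.78e-11, label = "OH self-reaction")
reaction <- function(reactants, products, k, label = "",
                     photon_driven = FALSE) {
  chk <- function(v, what) {
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop(what, " must be a named species -> stoichiometry vector",
           call. = FALSE)
    if (any(v <= 0)) stop(what, " stoichiometries must be positive",
                          call. = FALSE)
    v
  }
  reactants <- chk(unlist(reactants), "reactants")
  products <- chk(unlist(products), "products")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("rate coefficient k must be a single number >= 0", call. = FALSE)
  structure(
    list(reactants = reactants, products = products, k = k,
         label = label, photon_driven = isTRUE(photon_driven)),
    class = "ohkin_reaction"
  )
}

#' Assemble a reaction network
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects; every reaction may
#'   reference only listed species.
#' @param third_body_density Neutral third-body density M in cm^-3 at which
#'   three-body coefficients were folded (default 2.5e19, one atmosphere).
#' @param background_densities Named numeric vector of species held at fixed
#'   density during integration (e.g. the solvent).
#' @param alpha_override Optional effective OH recombination coefficient
#'   (cm^3 s^-1) recorded on the network for closed-form work; defaults to
#'   [alpha_oh()].
#' @return An object of class `ohkin_network`. Construction validates atom
#'   and charge balance of every reaction.
#' @export
reaction_network <- function(species, reactions,
                             third_body_density = 2.5e19,
                             background_densities = numeric(0),
                             alpha_override = NULL) {
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate species name: ", nm[duplicated(nm)][1], call. = FALSE)
  if (third_body_density <= 0)
    stop("third_body_density must be > 0", call. = FALSE)
  sp <- setNames(species, nm)
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    refs <- c(names(r$reactants), names(r$products))
    missing <- setdiff(refs, nm)
    if (length(missing) > 0)
      stop(sprintf("reactions[%d] ('%s') references unknown species: %s",
                   i, r$label, paste(missing, collapse = ", ")),
           call. = FALSE)
    bal <- reaction_balance(r, sp)
    if (!bal$ok)
      stop(sprintf("reactions[%d] ('%s') does not balance: %s",
                   i, r$label, bal$detail), call. = FALSE)
  }
  if (length(background_densities) > 0) {
    missing <- setdiff(names(background_densities), nm)
    if (length(missing) > 0)
      stop("background species not in network: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(species = sp, reactions = reactions,
         third_body_density = third_body_density,
         background_densities = background_densities,
         alpha_override = if (is.null(alpha_override)) alpha_oh()
                          else alpha_override),
    class = "ohkin_network"
  )
}

# Atom and charge balance of one reaction against a species table.
reaction_balance <- function(r, sp_table) {
  tally <- function(stoich) {
    atoms <- numeric(0)
    charge <- 0
    for (nm in names(stoich)) {
      s <- sp_table[[nm]]
      charge <- charge + s$charge * stoich[[nm]]
      for (el in names(s$composition)) {
        atoms[el] <- (if (el %in% names(atoms)) atoms[el] else 0) +
          s$composition[[el]] * stoich[[nm]]
      }
    }
    list(atoms = atoms, charge = charge)
  }
  lhs <- tally(r$reactants)
  rhs <- tally(r$products)
  els <- union(names(lhs$atoms), names(rhs$atoms))
  get0n <- function(a, el) if (el %in% names(a)) a[[el]] else 0
  for (el in els) {
    if (get0n(lhs$atoms, el) != get0n(rhs$atoms, el))
      return(list(ok = FALSE,
                  detail = sprintf("element %s: %g -> %g", el,
                                   get0n(lhs$atoms, el),
                                   get0n(rhs$atoms, el))))
  }
  if (lhs$charge != rhs$charge)
    return(list(ok = FALSE,
                detail = sprintf("charge: %d -> %d", lhs$charge, rhs$charge)))
  list(ok = TRUE, detail = "")
}

#' @export
print.ohkin_network <- function(x, ...) {
  cat(sprintf("<ohkin_network: %d species, %d reactions, M = %.3g cm^-3>\n",
              length(x$species), length(x$reactions), x$third_body_density))
  for (r in x$reactions) {
    side <- function(v) paste(
      ifelse(v > 1, paste0(v, " "), ""), names(v),
      sep = "", collapse = " + ")
    cat(sprintf("  %s -> %s   k = %.3g cm^3/s  [%s]\n",
                side(r$reactants), side(r$products), r$k, r$label))
  }
  invisible(x)
}

#' Build the default plasma-liquid OH reaction network
#'
#' The network carries the textually reported OH loss channels:
#' the ambient gas-phase self-reaction `OH + OH -> H2O2`
#' (k = 1.78e-11 cm^3/s), oxidation of hydrogen peroxide
#' `OH + H2O2 -> HO2 + H2O` (k = 1.7e-12 cm^3/s), the three-body
#' recombination `OH + OH + M -> H2O2 + M` folded to an effective two-body
#' coefficient k = 2.2e-11 cm^3/s at M = 2.5e19 cm^-3, and a secondary OH
#' loss channel with k = 2e-12 cm^3/s (the literature reports the
#' coefficient without resolvable products; a generic atom-balanced channel
#' `OH + OH -> H2O + O` is used). The effective recombination coefficient
#' for closed-form work is recorded as `alpha_override` and defaults to
#' [alpha_oh()] = 2.3e-11 cm^3/s.
#'
#' @param third_body_density Third-body density M, cm^-3.
#' @param alpha_override Effective OH recombination coefficient for the
#'   closed-form lifetime law; default [alpha_oh()].
#' @return An `ohkin_network` with 4 reactions over species
#'   OH, H2O2, HO2, H2O, O.
#' @export
#' @examples
#' net <- build_default_network()
#' net$reactions[[1]]$k    # 1.78e-11
build_default_network <- function(third_body_density = 2.5e19,
                                  alpha_override = NULL) {
  sp <- list(
    species("OH",   0L, c(H = 1, O = 1)),
    species("H2O2", 0L, c(H = 2, O = 2)),
    species("HO2",  0L, c(H = 1, O = 2)),
    species("H2O",  0L, c(H = 2, O = 1)),
    species("O",    0L, c(O = 1))
  )
  rx <- list(
    reaction(c(OH = 2), c(H2O2 = 1), k = 1.78e-11,
             label = "OH + OH -> H2O2 (ambient air)"),
    reaction(c(OH = 1, H2O2 = 1), c(HO2 = 1, H2O = 1), k = 1.7e-12,
             label = "OH + H2O2 -> HO2 + H2O"),
    reaction(c(OH = 2), c(H2O2 = 1), k = 2.2e-11,
             label = "OH + OH + M -> H2O2 + M (folded at M)"),
    reaction(c(OH = 2), c(H2O = 1, O = 1), k = 2e-12,
             label = "secondary OH loss channel")
  )
  reaction_network(sp, rx, third_body_density = third_body_density,
                   alpha_override = alpha_override)
}

#' Minimal OH-only quadratic-loss network
#'
#' A reduced network whose only process is OH self-recombination at the
#' effective coefficient `alpha`, so that the integrated trajectory must
#' follow the closed form `n0/(1 + alpha*n0*t)` exactly. Used for oracle
#' comparisons against [analytic_decay()].
#'
#' @param alpha Effective recombination coefficient, cm^3 s^-1.
#' @return An `ohkin_network` with species OH, H2O2 and one reaction.
#' @export
oh_recombination_network <- function(alpha = alpha_oh()) {
  reaction_network(
    list(species("OH", 0L, c(H = 1, O = 1)),
         species("H2O2", 0L, c(H = 2, O = 2))),
    list(reaction(c(OH = 2), c(H2O2 = 1), k = alpha,
                  label = "effective OH recombination")),
    alpha_override = alpha
  )
}

#' Define a source term
#'
#' Continuous sources inject `amplitude` cm^-3 s^-1 into the target species;
#' pulsed sources deposit `amplitude` cm^-3 instantaneously at each pulse
#' onset (the discharge current duration, ~2.1 us, is short compared to the
#' ~28.6 us inter-pulse period at 35 kHz).
#'
#' @param target Species name receiving the source.
#' @param mode `"continuous"` (amplitude in cm^-3 s^-1) or `"pulsed"`
#'   (amplitude is a per-pulse yield in cm^-3).
#' @param amplitude Nonnegative source strength; units depend on `mode`.
#' @param repetition_frequency Pulse repetition rate, Hz (default 35 kHz).
#' @param pulse_duration Discharge pulse duration, s (informational; pulses
#'   are deposited instantaneously).
#' @return An object of class `ohkin_source`.
#' @export
source_term <- function(target, mode = c("continuous", "pulsed"),
                        amplitude, repetition_frequency = 35000,
                        pulse_duration = 2.1e-6) {
  mode <- match.arg(mode)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (mode == "pulsed" && repetition_frequency <= 0)
    stop("repetition_frequency must be > 0 in pulsed mode", call. = FALSE)
  structure(
    list(target = target, mode = mode, amplitude = amplitude,
         repetition_frequency = repetition_frequency,
         pulse_duration = pulse_duration),
    class = "ohkin_source"
  )
}

#' Kinetic state: densities at one time
#'
#' @param time Time, s.
#' @param densities Named numeric vector, species -> density cm^-3; all
#'   entries must be >= 0.
#' @return An object of class `ohkin_state`.
#' @export
kinetic_state <- function(time = 0, densities) {
  densities <- unlist(densities)
  if (is.null(names(densities)) || any(!nzchar(names(densities))))
    stop("densities must be a named species -> cm^-3 vector", call. = FALSE)
  if (any(densities < 0))
    stop("densities must be >= 0", call. = FALSE)
  structure(list(time = time, densities = densities), class = "ohkin_state")
}

# Network config file (YAML or JSON) ---------------------------------------

#' Read a reaction network from a YAML/JSON config file
#'
#' The config carries `species:` entries (name, charge, composition) and
#' `reactions:` entries (reactants, products, k, label), plus optional
#' `third_body_density`, `background` and `alpha_override` keys. Validation
#' errors name the offending block.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ohkin_network`.
#' @export
read_network_config <- function(path) {
  if (!file.exists(path))
    stop("network config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  allowed <- c("species", "reactions", "third_body_density", "background",
               "alpha_override")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$species) || is.null(cfg$reactions))
    stop("config must define 'species:' and 'reactions:' blocks",
         call. = FALSE)
  sp <- lapply(seq_along(cfg$species), function(i) {
    s <- cfg$species[[i]]
    if (is.null(s$name))
      stop(sprintf("species[%d]: missing 'name'", i), call. = FALSE)
    species(s$name, charge = if (is.null(s$charge)) 0L else s$charge,
            composition = if (is.null(s$composition)) integer(0)
                          else unlist(s$composition))
  })
  rx <- lapply(seq_along(cfg$reactions), function(i) {
    r <- cfg$reactions[[i]]
    for (f in c("reactants", "products", "k"))
      if (is.null(r[[f]]))
        stop(sprintf("reactions[%d]: missing '%s'", i, f), call. = FALSE)
    reaction(unlist(r$reactants), unlist(r$products), k = r$k,
             label = if (is.null(r$label)) sprintf("reactions[%d]", i)
                     else r$label,
             photon_driven = isTRUE(r$photon_driven))
  })
  reaction_network(
    sp, rx,
    third_body_density = if (is.null(cfg$third_body_density)) 2.5e19
                         else cfg$third_body_density,
    background_densities = if (is.null(cfg$background)) numeric(0)
                           else unlist(cfg$background),
    alpha_override = cfg$alpha_override
  )
}
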