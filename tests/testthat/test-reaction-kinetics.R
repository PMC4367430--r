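test_that("default network carries the reported loss channels and balances atoms", {
  net <- build_default_network()
  expect_length(net$reactions, 4)
  ks <- vapply(net$reactions, function(r) r$k, numeric(1))
  expect_equal(sort(ks), sort(c(1.78e-11, 1.7e-12, 2.2e-11, 2e-12)))
  expect_equal(net$reactions[[1]]$k, 1.78e-11)
  expect_equal(net$third_body_density, 2.5e19)
  # effective recombination coefficient recorded for closed-form work
  expect_equal(net$alpha_override, 2.3e-11)
  # every reaction balances atoms and charge (constructor re-check)
  for (r in net$reactions)
    expect_true(reaction_balance(r, net$species)$ok)
})

test_that("unbalanced or ill-referenced reactions are rejected with names", {
  sp <- list(species("OH", 0L, c(H = 1, O = 1)),
             species("H2O2", 0L, c(H = 2, O = 2)))
  expect_error(
    reaction_network(sp, list(reaction(c(OH = 1), c(H2O2 = 1), 1e-11))),
    "does not balance")
  expect_error(
    reaction_network(sp, list(reaction(c(OH = 2), c(HO2 = 1), 1e-11))),
    "HO2")
  expect_error(reaction(c(OH = 2), c(H2O2 = 1), k = -1), "k must be")
})

test_that("rate_of_change follows the density-loss convention", {
  net <- oh_recombination_network(alpha = 2.3e-11)
  # all densities zero -> all derivatives zero
  dn0 <- rate_of_change(kinetic_state(0, c(OH = 0, H2O2 = 0)), net)
  expect_equal(unname(dn0), c(0, 0))
  # dn_OH/dt = -alpha * n^2 with the per-event factor absorbed into alpha
  dn <- rate_of_change(kinetic_state(0, c(OH = 1e16, H2O2 = 0)), net)
  expect_equal(dn[["OH"]], -2.3e-11 * (1e16)^2)
  # H2O2 forms at half the OH loss rate (atom bookkeeping)
  expect_equal(dn[["H2O2"]], -dn[["OH"]] / 2)
  # continuous source shifts the derivative by exactly +S
  src <- source_term("OH", "continuous", amplitude = 5e20)
  dn_s <- rate_of_change(kinetic_state(0, c(OH = 1e16, H2O2 = 0)), net, src)
  expect_equal(dn_s[["OH"]] - dn[["OH"]], 5e20)
  # unknown species named in the error
  expect_error(rate_of_change(kinetic_state(0, c(XYZ = 1)), net), "XYZ")
})

test_that("integration matches the closed-form quadratic decay", {
  n0 <- 4.2e16; alpha <- 2.3e-11
  tau <- predicted_lifetime(n0, alpha)
  net <- oh_recombination_network(alpha)
  t_grid <- seq(0, 10 * tau, length.out = 201)
  tr <- simulate(net, kinetic_state(0, c(OH = n0, H2O2 = 0)),
                 t_grid = t_grid)
  rel <- abs(tr$OH - analytic_decay(n0, alpha, t_grid)) / n0
  expect_lt(max(rel), 1e-6)
  # stoichiometric pairing along the trajectory: 2*dH2O2 + dOH = 0
  expect_lt(max(abs(2 * tr$H2O2 + tr$OH - n0)) / n0, 1e-6)
  expect_true(all(tr$OH >= 0))
})

test_that("zero initial densities stay identically zero", {
  net <- build_default_network()
  init <- kinetic_state(0, setNames(numeric(5), names(net$species)))
  tr <- simulate(net, init, t_grid = seq(0, 1e-5, length.out = 11))
  expect_true(all(as.matrix(tr[-1]) == 0))
})

test_that("closed networks conserve per-element atom totals", {
  net <- build_default_network()
  init <- kinetic_state(0, c(OH = 4.2e16, H2O2 = 1e15, HO2 = 0,
                             H2O = 0, O = 0))
  tr <- simulate(net, init, t_grid = seq(0, 5e-5, length.out = 51))
  tot <- element_totals(tr, net)
  for (el in c("H", "O")) {
    drift <- abs(tot[[el]] - tot[[el]][1]) / tot[[el]][1]
    expect_lt(max(drift), 1e-8)
  }
})

test_that("continuous sources superpose in the linear regime", {
  # at low density the quadratic loss is negligible: response is linear
  net <- oh_recombination_network(2.3e-11)
  grid <- seq(0, 1e-6, length.out = 21)
  run <- function(S) {
    simulate(net, kinetic_state(0, c(OH = 0, H2O2 = 0)),
             source = source_term("OH", "continuous", S), t_grid = grid)$OH
  }
  y1 <- run(1e10); y2 <- run(3e10); y12 <- run(4e10)
  expect_equal(y12, y1 + y2, tolerance = 1e-6)
})

test_that("pulsed sources deposit per-pulse yield at each onset", {
  net <- oh_recombination_network(2.3e-11)
  f <- 35000
  src <- source_term("OH", "pulsed", amplitude = 1e16,
                     repetition_frequency = f)
  grid <- sort(c(seq(0, 2.5 / f, length.out = 6),
                 1 / f + 1e-9, 2 / f + 1e-9))
  tr <- simulate(net, kinetic_state(0, c(OH = 0, H2O2 = 0)),
                 source = src, t_grid = grid)
  # first output point carries the first deposit
  expect_equal(tr$OH[1], 1e16)
  # density jumps back up after each onset: never decays to zero
  expect_true(all(tr$OH > 0))
  # just after the second onset the residual stacks on the fresh deposit
  expect_gt(max(tr$OH), 1.05e16)
})

test_that("hydroxide density follows pH through Avogadro conversion", {
  expect_equal(hydroxide_density_from_ph(7), 6.02214076e13,
               tolerance = 1e-9)
  expect_equal(hydroxide_density_from_ph(9), 6.02214076e15,
               tolerance = 1e-9)
  expect_equal(hydroxide_density_from_ph(14), 6.02214076e20,
               tolerance = 1e-9)
  ph <- seq(0, 14, by = 0.5)
  expect_true(all(diff(hydroxide_density_from_ph(ph)) > 0))
  expect_error(hydroxide_density_from_ph(14.5), "\\[0, 14\\]")
})

test_that("photodetachment has a hard 2.4 eV threshold and is linear in [OH-]", {
  expect_equal(photodetachment_source(1e20, 2.0, 1e18, 1e-16), 0)
  expect_equal(photodetachment_source(6.022e15, 4, 1e16, 1e-18),
               6.022e13)
  # just below / at threshold
  expect_equal(photodetachment_source(1e15, 2.399, 1e16, 1e-18), 0)
  expect_gt(photodetachment_source(1e15, 2.4, 1e16, 1e-18), 0)
  # doubling [OH-] doubles the source (pH 9 > pH 7 > pH 5 current ordering)
  s1 <- photodetachment_source(1e15, 4, 1e16, 1e-18)
  expect_equal(photodetachment_source(2e15, 4, 1e16, 1e-18), 2 * s1)
})

test_that("network config files round-trip through the YAML schema", {
  path <- system.file("extdata", "default_network.yaml", package = "ohkin")
  net <- read_network_config(path)
  ref <- build_default_network()
  expect_equal(length(net$reactions), length(ref$reactions))
  expect_equal(vapply(net$reactions, function(r) r$k, numeric(1)),
               vapply(ref$reactions, function(r) r$k, numeric(1)))
  expect_equal(net$alpha_override, 2.3e-11)
  # unknown top-level keys are named
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("species: []", "reactions: []", "bogus_key: 1"), bad)
  expect_error(read_network_config(bad), "bogus_key")
  # missing fields are located by block index
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("species:",
               "  - name: OH",
               "    composition: {H: 1, O: 1}",
               "reactions:",
               "  - reactants: {OH: 2}",
               "    k: 1.0e-11"), bad2)
  expect_error(read_network_config(bad2), "reactions\\[1\\].*products")
})
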