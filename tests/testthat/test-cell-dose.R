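test_that("membrane field and stress compose as 0.5*K*eps0*(dV/d)^2", {
  E <- membrane_field(0.25, 7e-9)
  # the 250 meV shift over a 7 nm membrane: ~35 MV/m
  expect_equal(E, 3.5714286e7, tolerance = 1e-6)
  expect_equal(E / 1e6, 35, tolerance = 0.03)
  expect_equal(membrane_field(0), 0)
  # linear in delta_v
  expect_equal(membrane_field(0.5), 2 * membrane_field(0.25))
  expect_error(membrane_field(0.25, 0), "> 0")
  # composition identity
  expect_equal(electric_stress(E, 5.8),
               0.5 * 5.8 * 8.8541878e-12 * (0.25 / 7e-9)^2)
  # direct evaluation at the quoted field: ~31 kPa
  expect_equal(electric_stress(3.5e7, 5.8), 3.1e4, tolerance = 0.02)
  expect_equal(electric_stress(0), 0)
  # quadratic in E
  expect_equal(electric_stress(2 * E), 4 * electric_stress(E))
})

test_that("secondary emission coefficient inverts its defining relation", {
  expect_equal(gamma_coefficient(1e-9, 1e-9), 0)
  # plasma-treated vs control membrane readings
  expect_equal(gamma_coefficient(1.12e-9, 1e-9), 0.12)
  expect_equal(gamma_coefficient(1.05e-9, 1e-9), 0.05)
  # exact inverse pair on a gamma grid
  for (g in c(0, 0.05, 0.12, 0.2, 1)) {
    I_i <- 2.3e-9
    expect_equal(gamma_coefficient((1 + g) * I_i, I_i), g)
  }
  expect_error(gamma_coefficient(1e-9, 0), "> 0")
})

test_that("discharge power integrates V*I over one period", {
  period <- 1 / 35000
  # DC waveform: P = V0*I0
  tt <- seq(0, period, length.out = 500)
  w <- discharge_waveform(tt, rep(10, 500), rep(0.5, 500))
  expect_equal(discharge_power(w), 5, tolerance = 1e-9)
  # zero current -> 0 W
  w0 <- discharge_waveform(tt, rep(1000, 500), rep(0, 500))
  expect_equal(discharge_power(w0), 0)
  # bipolar square: |V| = 1 kV, |I| = 34 mA during two 2.1 us pulses per
  # period, V*I > 0 in both half-cycles -> 2*1000*0.034*2.1e-6*35000 ~ 5 W
  eps <- 1e-12
  edges <- sort(c(0, 2.1e-6, 2.1e-6 + eps,
                  period / 2 - eps, period / 2, period / 2 + 2.1e-6,
                  period / 2 + 2.1e-6 + eps, period))
  V <- c(1000, 1000, 0, 0, -1000, -1000, 0, 0)
  I <- c(0.034, 0.034, 0, 0, -0.034, -0.034, 0, 0)
  wb <- discharge_waveform(edges, V, I)
  expect_equal(discharge_power(wb), 2 * 1000 * 0.034 * 2.1e-6 * 35000,
               tolerance = 1e-5)
  # linear in a voltage rescale
  wb2 <- discharge_waveform(edges, 3 * V, I)
  expect_equal(discharge_power(wb2), 3 * discharge_power(wb),
               tolerance = 1e-9)
  # waveform shorter than a period is refused
  expect_error(discharge_waveform(tt[1:100], rep(1, 100), rep(1, 100)),
               "period")
})

test_that("effective exposure time follows the duty-cycle convention", {
  T_eff <- effective_exposure_time(60, 35000, 3.92e-6)
  expect_equal(as.numeric(T_eff), 60 * 35000 * 3.92e-6)
  expect_equal(as.numeric(T_eff), 8.23, tolerance = 1e-3)
  expect_equal(attr(T_eff, "convention"), "duty")
  # radicals persisting the whole period: duty = 1
  f <- 35000
  expect_equal(as.numeric(effective_exposure_time(60, f, 1 / f)), 60)
  expect_equal(as.numeric(effective_exposure_time(60, 0, 1e-6)), 0)
  # alternative convention takes the raw treatment time
  expect_equal(as.numeric(effective_exposure_time(60, f, 1e-6, "exposure")),
               60)
})

test_that("nT dose criterion reproduces the depth-resolved outcomes", {
  # PBS densities at 2/4/6 mm under 60 s treatment
  n <- c(1.9e16, 0.5e16, 0.13e16)
  T_eff <- effective_exposure_time(60, 35000, 3.15e-6)
  das <- dose_criterion(n, T_eff, exposure = 60)
  expect_equal(das$apoptotic, c(TRUE, TRUE, FALSE))
  # zero density: zero dose, no flag
  z <- dose_criterion(0, T_eff, exposure = 60)
  expect_equal(z$dose_nT, 0)
  expect_false(z$apoptotic)
  # monotone nondecreasing in n at fixed T
  grid <- seq(0, 3e16, length.out = 30)
  flags <- dose_criterion(grid, T_eff, exposure = 60)$apoptotic
  expect_true(all(diff(as.integer(flags)) >= 0))
  # invariant under simultaneous unit rescaling of n and thresholds
  das2 <- dose_criterion(n * 1e-6, as.numeric(T_eff),
                         threshold_dose = 2.9e16 * 1e-6,
                         threshold_density = 0.3e16 * 1e-6, exposure = 60)
  expect_equal(das2$apoptotic, das$apoptotic)
})
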