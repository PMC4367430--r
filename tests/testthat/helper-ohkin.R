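# Shared fixtures, built in code.

# Depth-resolved OH densities (cm^-3) measured at 2/4/6 mm in the two
# solutions, and the matching measured lifetimes (s).
di_depth_profile <- function() {
  depth_profile(c(2, 4, 6), c(4.2e16, 1.3e16, 0.8e16), "DI")
}
pbs_depth_profile <- function() {
  depth_profile(c(2, 4, 6), c(1.9e16, 0.5e16, 0.1e16), "PBS")
}
lifetime_table <- function() {
  data.frame(n0_cm3 = c(4.2e16, 1.8e16, 0.8e16),
             tau_exp_s = c(3.15e-6, 3.61e-6, 3.92e-6),
             tau_theory_us = c(2.06, 4.82, 10.8))
}

# Noiseless hyperbolic trace on a uniform grid.
clean_trace <- function(n0 = 4.2e16, alpha = alpha_oh(),
                        dt = 2e-8, t_max = 2e-5) {
  tt <- seq(0, t_max, by = dt)
  decay_trace(tt, analytic_decay(n0, alpha, tt))
}

# Independent least-squares line (the oracle for fit_attenuation): plain
# normal-equation slope/intercept in (depth_cm, log density).
ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}
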