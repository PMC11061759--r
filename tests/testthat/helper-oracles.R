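# Shared fixtures and independent oracles used across test files.

# Independent oracle for the Burgers governing equation: instead of the
# closed-form creep solution, integrate the mechanical network state-space
# (Maxwell dashpot strain eD, Kelvin-Voigt strain eK) with a stiff ODE
# solver for an arbitrary stress history sigma_fun(t).
ode_strain_oracle <- function(params, sigma_fun, times,
                              rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) {
    s <- sigma_fun(t)
    list(c(s / params$eta2, (s - params$E1 * y[2]) / params$eta1))
  }
  sol <- deSolve::ode(c(eD = 0, eK = 0), times, rhs, NULL,
                      rtol = rtol, atol = atol)
  sigma_fun(times) / params$E2 + sol[, "eD"] + sol[, "eK"]
}

# Random physically plausible Burgers parameter sets: moduli in the
# 1e2-1e3 Pa range and a retardation time of tens of seconds, i.e. well
# inside a 480-s acquisition window.
random_burgers <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      E1 <- 10^stats::runif(1, log10(300), log10(5000))
      E2 <- 10^stats::runif(1, log10(300), log10(5000))
      tau1 <- stats::runif(1, 10, 60)
      eta2 <- 10^stats::runif(1, 5, 6)
      burgers_params(E1 = E1, E2 = E2, eta1 = tau1 * E1, eta2 = eta2)
    })
  })
}

# Complex-ratio oracle for the frequency-domain moduli: Fourier transform
# of the governing equation, independent of the printed storage/loss forms.
complex_ratio_oracle <- function(params, omega) {
  tc <- burgers_times(params)
  (1i * omega * params$eta2 - tc[["tau1"]] * params$eta2 * omega^2) /
    (1 + tc[["kappa1"]] * 1i * omega - tc[["tau1"]] * tc[["tau3"]] * omega^2)
}

# Frequencies within the central two decades of a log-spaced grid
# (a two-decade band centred on the grid's geometric mean).
central_two_decades <- function(omega) {
  mid <- sqrt(prod(range(omega)))
  omega >= mid / 10 & omega <= mid * 10
}

# Minimal analysis config as an in-memory list.
test_config <- function(...) {
  utils::modifyList(
    list(coverslip_mass_kg = 1e-6, coverslip_volume_m3 = 2e-10,
         fluid_density_kg_m3 = 1005, pixel_size_um = 2.5,
         frame_interval_s = 2, strain_convention = "engineering"),
    list(...))
}
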