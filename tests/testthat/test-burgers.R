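test_that("creep strain matches limits and an independent ODE integration", {
  p <- burgers_params(E1 = 1000, E2 = 1000, eta1 = 1e4, eta2 = 1e5)
  s0 <- 100
  # instantaneous elastic jump from the Maxwell spring
  expect_equal(creep_strain(p, s0, 0), s0 / p$E2)
  # terminal flow: late-time strain rate tends to sigma0/eta2
  tt <- c(5000, 5001)
  expect_equal(diff(creep_strain(p, s0, tt)), s0 / p$eta2, tolerance = 1e-6)
  # stiff-ODE oracle of the governing equation at t = 50 s
  skip_if_not_installed("deSolve")
  eps_ode <- ode_strain_oracle(p, function(t) rep(s0, length(t)), c(0, 50))[2]
  expect_equal(creep_strain(p, s0, 50), eps_ode, tolerance = 1e-6)
  # non-decreasing in t, linear in sigma0
  tgrid <- seq(0, 400, 4)
  eps <- creep_strain(p, s0, tgrid)
  expect_true(all(diff(eps) > 0))
  expect_equal(creep_strain(p, 2 * s0, tgrid), 2 * eps)
  expect_error(burgers_params(-1, 1, 1, 1), "positive")
})

test_that("hereditary strain response reduces to creep and matches the ODE", {
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  tt <- seq(0, 478, 2)
  # constant stress -> identical to the closed-form creep at all samples
  const <- strain_response(p, tt, rep(300, length(tt)))
  expect_equal(const, creep_strain(p, 300, tt), tolerance = 1e-12)
  # linearity: doubling the stress history doubles the strain
  sig <- 300 * exp(-tt / 350)
  expect_equal(strain_response(p, tt, 2 * sig),
               2 * strain_response(p, tt, sig), tolerance = 1e-12)
  # staircase stress vs fine-grid ODE integration of the governing equation
  skip_if_not_installed("deSolve")
  sig_stair <- 300 * (1 - 0.3 * floor(tt / 120) / 4)
  sfun <- stats::approxfun(tt, sig_stair, method = "linear", rule = 2)
  eps_ode <- ode_strain_oracle(p, sfun, tt)
  eps_her <- strain_response(p, tt, sig_stair)
  expect_lt(max(abs(eps_her[-1] / eps_ode[-1] - 1)), 0.005)
  expect_error(strain_response(p, 0, 100), "two samples")
})

test_that("frequency-domain moduli match the printed closed form and the
           complex-ratio oracle", {
  # hand-evaluated point: all time constants 1 s, eta2 = 1 Pa s, w = 1
  p1 <- burgers_params(E1 = 1, E2 = 1, eta1 = 1, eta2 = 1)
  m1 <- burgers_moduli(p1, 1)
  expect_equal(m1$storage_Pa, 1 / 3)
  expect_equal(m1$loss_Pa, 1 / 3)
  expect_equal(m1$tan_delta, 1)
  # low-frequency leading order: E' ~ eta2 (tau2+tau3) w^2, E'' ~ eta2 w
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  tc <- burgers_times(p)
  w0 <- 1e-7
  m0 <- burgers_moduli(p, w0)
  expect_equal(m0$storage_Pa, p$eta2 * (tc[["tau2"]] + tc[["tau3"]]) * w0^2,
               tolerance = 1e-4)
  expect_equal(m0$loss_Pa, p$eta2 * w0, tolerance = 1e-4)
  # equivalence with the complex ratio for 1000 random parameter sets
  w <- 10^seq(-4, 1, length.out = 13)
  for (pr in random_burgers(1000)) {
    m <- burgers_moduli(pr, w)
    ref <- complex_ratio_oracle(pr, w)
    expect_equal(m$storage_Pa, Re(ref), tolerance = 1e-12)
    expect_equal(m$loss_Pa, Im(ref), tolerance = 1e-12)
  }
  expect_error(burgers_moduli(p, c(-1, 1)), "positive")
})

test_that("loss tangent is the loss/storage ratio with guarded points", {
  p <- burgers_params(E1 = 1, E2 = 1, eta1 = 1, eta2 = 1)
  lt <- loss_tangent(burgers_moduli(p, 1))
  expect_equal(lt$tan_delta, 1)
  # nearly elastic limit: huge terminal viscosity and frequencies well above
  # the retardation rate leave both arms effectively frozen -> tan(delta) ~ 0
  pe <- burgers_params(E1 = 1000, E2 = 1000, eta1 = 1e4, eta2 = 1e12)
  lte <- loss_tangent(burgers_moduli(pe, 10^seq(2, 3, 0.5)))
  expect_true(all(lte$tan_delta < 2e-3))
  # non-positive storage points are excluded with a message
  sp <- modulus_spectrum(c(1, 2), c(-1, 5), c(1, 5))
  expect_message(out <- loss_tangent(sp), "excluded")
  expect_equal(out$omega_rad_s, 2)
})

test_that("time constants are derived fresh and reporting conventions swap", {
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  tc <- burgers_times(p)
  expect_equal(tc[["tau1"]], 2.67e5 / 2500)
  expect_equal(tc[["tau2"]], 8e5 / 2500)
  expect_equal(tc[["tau3"]], 8e5 / 1200)
  expect_equal(tc[["kappa1"]], sum(tc[c("tau1", "tau2", "tau3")]))
  req <- burgers_report(p, "as_equation")
  rdis <- burgers_report(p, "as_discussion")
  expect_equal(req[["eta1"]], p$eta1)
  expect_equal(req[["tau2"]], p$eta2 / p$E2)
  expect_equal(rdis[["eta1"]], p$eta2)
  expect_equal(rdis[["E1"]], p$E2)
  expect_equal(rdis[["tau2"]], p$eta1 / p$E1)
})

test_that("time-domain fitting recovers generating parameters", {
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  tt <- seq(0, 478, 2)
  eps <- creep_strain(p, 300, tt)
  ser <- data.frame(time_s = tt, stress_Pa = 300, strain = eps)
  fit <- fit_burgers(ser, mode = "constant_stress")
  for (nm in c("E1", "E2", "eta1", "eta2"))
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-3)
  expect_true(fit$converged)
  expect_lt(fit$residual_norm, 1e-6)
  expect_true(all(is.finite(fit$se)))
  # moderate noise: each parameter within 15% in log distance (fixed seed)
  eps_n <- withr::with_seed(99, eps * (1 + stats::rnorm(length(tt), 0, 0.02)))
  fit_n <- fit_burgers(data.frame(time_s = tt, stress_Pa = 300,
                                  strain = eps_n))
  for (nm in c("E1", "E2", "eta1", "eta2"))
    expect_lt(abs(log(fit_n$params[[nm]] / p[[nm]])), 0.15)
  # degenerate flat strain errors out
  expect_error(fit_burgers(data.frame(time_s = tt, stress_Pa = 300,
                                      strain = rep(0.2, length(tt)))),
               "flat strain")
})

test_that("spectrum fitting recovers the reporting triple", {
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  w <- 10^seq(-3, 1, length.out = 40)
  spec <- burgers_moduli(p, w)
  sf <- fit_spectrum(spec)
  expect_equal(unname(sf$triple),
               unname(burgers_report(p)), tolerance = 1e-2)
  # scaling the spectrum scales the moduli-dimension parameters, not tau2
  spec2 <- modulus_spectrum(w, 2 * spec$storage_Pa, 2 * spec$loss_Pa)
  sf2 <- fit_spectrum(spec2)
  expect_equal(sf2$triple[["eta1"]] / sf$triple[["eta1"]], 2, tolerance = 1e-2)
  expect_equal(sf2$triple[["E1"]] / sf$triple[["E1"]], 2, tolerance = 1e-2)
  expect_equal(sf2$triple[["tau2"]], sf$triple[["tau2"]], tolerance = 1e-2)
  # a white-noise "spectrum" is not Burgers-like and must be rejected
  noise <- withr::with_seed(5, modulus_spectrum(
    w, 10^stats::runif(40, 0, 3), 10^stats::runif(40, 0, 3)))
  expect_error(fit_spectrum(noise), "converge")
})
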