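test_that("compressional-to-shear conversion matches E = 2G(1+nu)", {
  # worked examples at nu = 0.4 (division by exactly 2.8)
  expect_equal(compressional_to_shear(5.15e2, 0.4), 5.15e2 / 2.8)
  expect_equal(compressional_to_shear(5.15e2, 0.4) / 100, 1.83,
               tolerance = 0.01 / 1.83)
  expect_equal(compressional_to_shear(3.46e2, 0.4) / 100, 1.23,
               tolerance = 0.01 / 1.23)
  # incompressible limit: divisor exactly 3
  expect_equal(compressional_to_shear(3, 0.5), 1)
  expect_error(compressional_to_shear(1, 0.6), "Poisson")
  expect_error(compressional_to_shear(1, -1), "Poisson")
  # round trip E -> G -> E is the identity for any nu
  for (nu in c(-0.5, 0, 0.3, 0.4, 0.5))
    expect_equal(shear_to_compressional(compressional_to_shear(515, nu), nu),
                 515)
})

test_that("spectrum conversion preserves the grid and relabels the kind", {
  p <- burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)
  w <- 10^seq(-2, 0, length.out = 15)
  e <- burgers_moduli(p, w)
  g <- compressional_to_shear(e, nu = 0.4)
  expect_equal(g$kind, rep("shear", 15))
  expect_equal(g$omega_rad_s, e$omega_rad_s)
  expect_equal(g$storage_Pa, e$storage_Pa / 2.8)
  expect_equal(g$tan_delta, e$tan_delta)  # ratio is conversion-invariant
  back <- shear_to_compressional(g, nu = 0.4)
  expect_equal(back$storage_Pa, e$storage_Pa)
})

test_that("Poisson sensitivity matches the closed form", {
  expect_equal(poisson_sensitivity(0.4, 0.5), 1 - 1.4 / 1.5)
  expect_equal(poisson_sensitivity(0.4, 0.5), 0.0667, tolerance = 1e-2)
  expect_equal(poisson_sensitivity(0.3, 0.3), 0)
  expect_equal(poisson_sensitivity(0.0, 0.5), 1 / 3, tolerance = 1e-9)
})

test_that("nanoindentation moduli invert the Hertz linearisation", {
  # forward-generate displacement from a known shear Burgers response via
  # the same linearisation, then invert
  pG <- burgers_params(E1 = 900, E2 = 430, eta1 = 9.5e4, eta2 = 2.9e5)
  R <- 23e-6; d0 <- 6e-6; nu <- 0.5; F0 <- 2e-6
  pref <- (1 - nu) / (4 * sqrt(R * d0))
  tt <- seq(0, 478, 2)
  # displacement creep under the linearised contact: delta = F0 pref J_shear
  delta <- F0 * pref * creep_compliance(pG, tt)
  rec <- indentation_record(tt, rep(F0, length(tt)), delta,
                            tip_radius = R, poisson = nu,
                            operating_depth = d0)
  w <- default_frequency_grid(tt)
  mid <- central_two_decades(w)
  got <- indentation_moduli(rec, w)
  want <- burgers_moduli(pG, got$omega_rad_s)
  expect_lt(max(abs(got$storage_Pa[mid] / want$storage_Pa[mid] - 1)), 0.02)
  expect_lt(max(abs(got$loss_Pa[mid] / want$loss_Pa[mid] - 1)), 0.05)
  # linearity: doubling the load doubles G* at fixed displacement
  rec2 <- indentation_record(tt, rep(2 * F0, length(tt)), delta,
                             tip_radius = R, poisson = nu,
                             operating_depth = d0)
  got2 <- indentation_moduli(rec2, w)
  expect_equal(got2$storage_Pa, 2 * got$storage_Pa, tolerance = 1e-9)
  # Poisson prefactor: nu 0.5 vs 0.4 changes G* by (1-0.5)/(1-0.4)
  rec3 <- indentation_record(tt, rep(F0, length(tt)), delta,
                             tip_radius = R, poisson = 0.4,
                             operating_depth = d0)
  got3 <- indentation_moduli(rec3, w)
  expect_equal(got$storage_Pa / got3$storage_Pa,
               rep(0.5 / 0.6, nrow(got)), tolerance = 1e-9)
})

test_that("indentation CSV reader handles both load units", {
  tt <- seq(0, 38, 2)
  df <- data.frame(time_s = tt, load_uN = rep(2, 20),
                   displacement_m = seq(1e-6, 2e-6, length.out = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  rec <- read_indentation(path, tip_radius = 23e-6)
  expect_equal(rec$load, rep(2e-6, 20))
  expect_equal(rec$operating_depth, mean(df$displacement_m))
  df$load_uN <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_indentation(path, tip_radius = 23e-6), "load_N")
})

test_that("group summaries and Welch comparisons behave as documented", {
  x <- withr::with_seed(3, stats::rnorm(17, 5, 2))
  gs <- group_summary(x, "demo", "eta1")
  expect_equal(gs$mean, mean(x))
  expect_equal(gs$sem, stats::sd(x) / sqrt(17))   # brute-force SEM
  expect_equal(gs$n, 17)
  expect_equal(group_summary(3.2)$sem, 0)
  # identical groups: p = 1, not significant
  same <- c(1, 2, 3, 4)
  expect_equal(compare_groups(same, same)$p_value, 1)
  expect_equal(compare_groups(same, same)$label, "ns")
  # well-separated groups: strongly significant
  cmp <- compare_groups(c(1, 1.1, 0.9), c(10, 10.1, 9.9))
  expect_lt(cmp$p_value, 0.005)
  expect_equal(cmp$label, "**")
  expect_match(cmp$method, "Welch")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
  # star thresholds
  expect_equal(significance_label(0.04), "*")
  expect_equal(significance_label(0.004), "**")
  expect_equal(significance_label(0.2), "ns")
})
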