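#' Convert compressional moduli to shear moduli
#'
#' For an isotropic linear-elastic (or linear-viscoelastic, frequency by
#' frequency) material, `E = 2 G (1 + nu)` with `nu` the Poisson ratio, so
#' `G = E / (2 (1 + nu))`. With the commonly assumed `nu = 0.4` this is
#' division by exactly 2.8; with the incompressible limit `nu = 0.5`,
#' division by 3.
#'
#' @param E compressional modulus (Pa, scalar or vector), or a
#'   [modulus_spectrum()] whose storage and loss moduli are converted
#'   element-wise (the result has `kind = "shear"`).
#' @param nu Poisson ratio, in `(-1, 0.5]`.
#' @return Shear modulus values, or a shear [modulus_spectrum()].
#' @export
compressional_to_shear <- function(E, nu = 0.4) {
  check_poisson(nu)
  if (inherits(E, "modulus_spectrum")) {
    return(modulus_spectrum(E$omega_rad_s,
                            E$storage_Pa / (2 * (1 + nu)),
                            E$loss_Pa / (2 * (1 + nu)),
                            kind = "shear",
                            extrapolated = if ("extrapolated" %in% names(E))
                              E$extrapolated))
  }
  stopifnot(all(E >= 0))
  E / (2 * (1 + nu))
}

#' @rdname compressional_to_shear
#' @param G shear modulus (Pa) or shear [modulus_spectrum()].
#' @export
shear_to_compressional <- function(G, nu = 0.4) {
  check_poisson(nu)
  if (inherits(G, "modulus_spectrum")) {
    return(modulus_spectrum(G$omega_rad_s,
                            G$storage_Pa * 2 * (1 + nu),
                            G$loss_Pa * 2 * (1 + nu),
                            kind = "compressional",
                            extrapolated = if ("extrapolated" %in% names(G))
                              G$extrapolated))
  }
  G * 2 * (1 + nu)
}

check_poisson <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) ||
      nu <= -1 || nu > 0.5)
    stop("Poisson ratio must be a single value in (-1, 0.5]")
  invisible(nu)
}

#' Sensitivity of the converted shear modulus to the Poisson ratio
#'
#' For a fixed compressional modulus, changing the assumed Poisson ratio
#' from `nu_a` to `nu_b` rescales `G` by `(1+nu_a)/(1+nu_b)`; the fractional
#' decrease is `1 - (1+nu_a)/(1+nu_b)`. Moving from the commonly assumed 0.4
#' to the incompressible 0.5 decreases the moduli by `1 - 1.4/1.5`, about
#' 6.7%.
#'
#' @param nu_a,nu_b Poisson ratios, each in `(-1, 0.5]`.
#' @return Fractional change in `G` at fixed `E` (positive = decrease).
#' @export
poisson_sensitivity <- function(nu_a, nu_b) {
  check_poisson(nu_a); check_poisson(nu_b)
  1 - (1 + nu_a) / (1 + nu_b)
}

#' Nanoindentation creep record
#'
#' Sampled load and displacement histories from a load-controlled
#' (creep) nanoindentation test with a spherical tip.
#'
#' @param times sample times, s, strictly increasing.
#' @param load applied load `F(t)`, N.
#' @param displacement indentation depth `delta(t)`, m (>= 0).
#' @param tip_radius spherical tip radius, m (> 0).
#' @param poisson Poisson ratio of the sample (default 0.5).
#' @param operating_depth linearisation depth `delta0`, m; default the mean
#'   displacement over the record (the hold depth).
#' @return An object of class `indentation_record`.
#' @export
indentation_record <- function(times, load, displacement, tip_radius,
                               poisson = 0.5, operating_depth = NULL) {
  stopifnot(length(times) == length(load),
            length(times) == length(displacement))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (tip_radius <= 0) stop("tip radius must be strictly positive")
  if (any(displacement < 0)) stop("displacement must be non-negative")
  check_poisson(poisson)
  if (is.null(operating_depth)) operating_depth <- mean(displacement)
  if (operating_depth <= 0) stop("operating depth must be strictly positive")
  structure(list(times = times, load = load, displacement = displacement,
                 tip_radius = tip_radius, poisson = poisson,
                 operating_depth = operating_depth),
            class = "indentation_record")
}

#' Shear moduli from a nanoindentation creep record
#'
#' Converts sampled load and displacement histories to a frequency-dependent
#' shear modulus using the model-free sampled Fourier transform of both
#' signals and a linearised Hertzian spherical contact about the operating
#' depth `delta0`: small oscillations obey
#' `dF = 2 sqrt(R delta0) E/(1 - nu^2) ddelta`, giving
#'
#' \deqn{G^*(\omega) = \frac{(1-\nu)\,\hat F(\omega)}
#'                          {4\sqrt{R\,\delta_0}\,\hat\delta(\omega)}.}
#'
#' This first-order linearisation is one defensible reading of
#' i-Rheo-style indentation analysis; it is isolated in this single
#' function so an alternative contact prefactor can be swapped in.
#'
#' @param rec an [indentation_record()].
#' @param omega angular frequency grid; default from the record's times.
#' @param ... passed to [default_frequency_grid()].
#' @return A shear [modulus_spectrum()] with an `extrapolated` column.
#' @export
indentation_moduli <- function(rec, omega = NULL, ...) {
  stopifnot(inherits(rec, "indentation_record"))
  if (is.null(omega)) omega <- default_frequency_grid(rec$times, ...)
  fF <- sampled_fourier(sampled_signal(rec$times, rec$load), omega)
  fD <- sampled_fourier(sampled_signal(rec$times, rec$displacement), omega)
  ok <- Mod(fD) > 1e-12 * Mod(fF)
  if (!all(ok))
    message(sum(!ok), " frequency point(s) excluded: displacement transform ",
            "magnitude below threshold")
  pref <- (1 - rec$poisson) / (4 * sqrt(rec$tip_radius * rec$operating_depth))
  gstar <- pref * fF[ok] / fD[ok]
  dt <- stats::median(diff(rec$times))
  fundamental <- 2 * pi / (diff(range(rec$times)) + dt)
  modulus_spectrum(omega[ok], Re(gstar), Im(gstar), kind = "shear",
                   extrapolated = omega[ok] < fundamental * (1 - 1e-9))
}

#' Read a nanoindentation creep CSV
#'
#' Columns `time_s`, `displacement_m`, and either `load_N` or `load_uN`
#' (micro-newtons, converted on reading). Tip radius and Poisson ratio are
#' instrument/sample properties supplied by the caller.
#'
#' @param path CSV path.
#' @param tip_radius spherical tip radius, m.
#' @param poisson Poisson ratio (default 0.5).
#' @return An [indentation_record()].
#' @export
read_indentation <- function(path, tip_radius, poisson = 0.5) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "displacement_m") %in% names(df)))
    stop("indentation CSV must have columns time_s and displacement_m")
  load <- if ("load_N" %in% names(df)) df$load_N
  else if ("load_uN" %in% names(df)) df$load_uN * 1e-6
  else stop("indentation CSV must have a load_N or load_uN column")
  indentation_record(df$time_s, load, df$displacement_m,
                     tip_radius = tip_radius, poisson = poisson)
}

#' Per-group summary as mean +/- SEM
#'
#' @param values numeric sample (n >= 1).
#' @param label group label.
#' @param parameter name of the summarised parameter.
#' @return One-row data.frame with columns `label`, `parameter`, `mean`,
#'   `sem` (sample standard deviation / sqrt(n); 0 when n = 1) and `n`.
#' @export
group_summary <- function(values, label = "group", parameter = "value") {
  stopifnot(is.numeric(values), length(values) >= 1)
  n <- length(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else 0
  data.frame(label = label, parameter = parameter,
             mean = mean(values), sem = sem, n = n)
}

#' Two-group comparison with significance stars
#'
#' Welch's two-sample two-sided t-test (unequal variances), with the star
#' labelling `**` for p < 0.005, `*` for p < 0.05, and `ns` otherwise.
#'
#' @param a,b numeric samples, at least 3 values each.
#' @return List with `p_value`, `label`, `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("at least 3 observations per group are required")
  ht <- stats::t.test(a, b)
  list(p_value = ht$p.value, label = significance_label(ht$p.value),
       mean_a = mean(a), mean_b = mean(b), method = ht$method)
}

#' @rdname compare_groups
#' @param p a p-value.
#' @export
significance_label <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 0.005) "**" else if (p < 0.05) "*" else "ns"
}
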