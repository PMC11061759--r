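#' Sampled time signal with end-point metadata
#'
#' Container for a discretely sampled time function `g(t)` together with the
#' two quantities the sampled Fourier transform needs beyond the samples
#' themselves: the value at time zero `g(0)` and the terminal gradient
#' (long-time slope) `gdot_inf`.
#'
#' Defaults: `g(0)` is the first sample when the record starts at `t = 0`,
#' otherwise the linear extrapolation of the first two samples back to
#' `t = 0`; `gdot_inf` is the least-squares slope over the final 20% of the
#' samples. Both can be overridden.
#'
#' @param times strictly increasing sample times, s (first time >= 0).
#' @param values samples of the signal.
#' @param value_at_zero optional override for `g(0)`.
#' @param terminal_gradient optional override for `gdot_inf` (may be 0).
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(times, values, value_at_zero = NULL,
                           terminal_gradient = NULL) {
  stopifnot(length(times) == length(values))
  if (length(times) < 4) stop("at least 4 samples are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] < 0) stop("times must be non-negative")
  if (is.null(value_at_zero)) {
    value_at_zero <- if (times[1] == 0) values[1]
    else values[1] - times[1] * (values[2] - values[1]) / (times[2] - times[1])
  }
  if (is.null(terminal_gradient)) {
    n <- length(times)
    idx <- seq.int(max(1, floor(0.8 * n)), n)
    terminal_gradient <-
      stats::lm.fit(cbind(1, times[idx]), values[idx])$coefficients[[2]]
  }
  if (!is.finite(terminal_gradient))
    stop("terminal gradient must be finite")
  structure(list(times = times, values = values,
                 value_at_zero = value_at_zero,
                 terminal_gradient = terminal_gradient),
            class = "sampled_signal")
}

as_sampled_signal <- function(x, times = NULL, ...) {
  if (inherits(x, "sampled_signal")) return(x)
  if (is.data.frame(x)) {
    vcol <- setdiff(names(x), "time_s")[1]
    return(sampled_signal(x$time_s, x[[vcol]], ...))
  }
  sampled_signal(times, x, ...)
}

#' Fourier transform of a sampled time function
#'
#' Evaluates `-w^2 ghat(w)` for a function known only through discrete
#' samples, assuming the function is piecewise linear between samples,
#' extends from its extrapolated value `g(0)` at time zero, and continues
#' beyond the last sample with constant gradient `gdot_inf`:
#'
#' \deqn{-\omega^2\hat g(\omega) = i\omega g(0)
#'   + (1-e^{-i\omega t_1})\frac{g_1-g(0)}{t_1}
#'   + \dot g_\infty e^{-i\omega t_N}
#'   + \sum_{k=2}^{N}\frac{g_k-g_{k-1}}{t_k-t_{k-1}}
#'     (e^{-i\omega t_{k-1}}-e^{-i\omega t_k}).}
#'
#' The formula is exact for constant signals and pure ramps; for smooth
#' signals the error is the piecewise-linear interpolation error. No
#' windowing or FFT is involved, so any positive frequency may be evaluated,
#' including below the record's fundamental frequency (such points should be
#' treated as extrapolation).
#'
#' @param sig a [sampled_signal()] (a record starting at `t = 0` is handled
#'   by taking `g(0)` from the first sample).
#' @param omega angular frequencies, rad/s (> 0).
#' @return Complex vector of `-w^2 ghat(w)` values, one per frequency.
#' @export
sampled_fourier <- function(sig, omega) {
  sig <- as_sampled_signal(sig)
  if (any(omega <= 0)) stop("omega must be strictly positive")
  t <- sig$times
  g <- sig$values
  g0 <- sig$value_at_zero
  if (t[1] == 0) {  # the t = 0 sample carries g(0); the series starts at t2
    t <- t[-1]
    g <- g[-1]
  }
  n <- length(t)
  slopes <- diff(g) / diff(t)
  vapply(omega, function(w) {
    e <- exp(-1i * w * t)
    acc <- 1i * w * g0 +
      (1 - e[1]) * (g[1] - g0) / t[1] +
      sig$terminal_gradient * e[n]
    if (n > 1) acc <- acc + sum(slopes * (e[-n] - e[-1]))
    acc
  }, complex(1))
}

#' Default logarithmic frequency grid for a sampled record
#'
#' Log-spaced grid (20 points per decade by default) spanning the
#' fundamental frequency of the record, `2*pi/T` with `T` the record length
#' including one sample interval, up to the Nyquist limit `pi/dt` with `dt`
#' the median sampling interval. `extend_low_decades` pushes the lower edge
#' down by whole decades; such frequencies are below the fundamental and are
#' flagged as extrapolated by [complex_modulus()].
#'
#' @param times sample times, s (>= 4 samples).
#' @param points_per_decade grid density (default 20).
#' @param extend_low_decades non-negative number of decades to extend below
#'   the fundamental (default 0).
#' @return Increasing numeric vector of angular frequencies, rad/s.
#' @export
default_frequency_grid <- function(times, points_per_decade = 20,
                                   extend_low_decades = 0) {
  stopifnot(length(times) >= 4, extend_low_decades >= 0)
  dt <- stats::median(diff(times))
  duration <- diff(range(times)) + dt
  lo <- 2 * pi / duration / 10^extend_low_decades
  hi <- pi / dt
  10^seq(log10(lo), log10(hi), by = 1 / points_per_decade)
}

#' Model-free complex modulus from sampled stress and strain
#'
#' Evaluates the complex modulus as the ratio of the sampled Fourier
#' transforms of stress and strain, `E*(w) = sigmahat(w) / epshat(w)`
#' (the `-w^2` factors of [sampled_fourier()] cancel). The storage modulus
#' is the real part and the loss modulus the imaginary part. No constitutive
#' model is assumed: this is the model-free (i-Rheo) analysis route.
#'
#' Stress and strain must share a time grid; if they do not, the strain is
#' resampled onto the stress grid by linear interpolation. Frequencies where
#' the strain transform magnitude falls below `1e-12` times the stress
#' transform magnitude are excluded. Frequencies below the record's
#' fundamental (`2*pi/T`) are flagged in the `extrapolated` column. Negative
#' storage or loss values are retained but reported with a message.
#'
#' @param stress stress record: a [sampled_signal()], or a `stress_strain`
#'   data.frame (in which case `strain` may be omitted).
#' @param strain strain record (engineering convention), as for `stress`.
#' @param omega angular frequency grid; default [default_frequency_grid()]
#'   of the stress record.
#' @param ... passed to [default_frequency_grid()].
#' @return A [modulus_spectrum()] with an `extrapolated` column.
#' @export
complex_modulus <- function(stress, strain = NULL, omega = NULL, ...) {
  if (is.data.frame(stress) && inherits(stress, "stress_strain")) {
    series <- as_engineering(stress)
    strain <- sampled_signal(series$time_s, series$strain)
    stress <- sampled_signal(series$time_s, series$stress_Pa)
  } else {
    stress <- as_sampled_signal(stress)
    strain <- as_sampled_signal(strain)
  }
  if (!isTRUE(all.equal(stress$times, strain$times))) {
    vals <- stats::approx(strain$times, strain$values,
                          xout = stress$times, rule = 2)$y
    strain <- sampled_signal(stress$times, vals)
  }
  if (is.null(omega)) omega <- default_frequency_grid(stress$times, ...)
  fs <- sampled_fourier(stress, omega)
  fe <- sampled_fourier(strain, omega)
  ok <- Mod(fe) > 1e-12 * Mod(fs)
  if (!all(ok))
    message(sum(!ok), " frequency point(s) excluded: strain transform ",
            "magnitude below threshold")
  estar <- fs[ok] / fe[ok]
  if (any(Re(estar) < 0) || any(Im(estar) < 0))
    message("negative storage or loss values present in the model-free ",
            "spectrum (reported as-is; often an edge/extrapolation artefact)")
  dt <- stats::median(diff(stress$times))
  fundamental <- 2 * pi / (diff(range(stress$times)) + dt)
  modulus_spectrum(omega[ok], Re(estar), Im(estar),
                   kind = "compressional",
                   extrapolated = omega[ok] < fundamental * (1 - 1e-9))
}
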