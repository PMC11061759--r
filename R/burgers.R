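#' Four-element Burgers model parameters
#'
#' The Burgers material is a Maxwell element (spring `E2`, dashpot `eta2`) in
#' series with a Kelvin-Voigt element (spring `E1`, dashpot `eta1`). Its
#' governing one-dimensional equation is
#'
#' \deqn{\sigma + (\eta_1/E_1 + \eta_2/E_1 + \eta_2/E_2)\dot\sigma +
#'       (\eta_1\eta_2)/(E_1 E_2)\ddot\sigma =
#'       \eta_2\dot\varepsilon + (\eta_1/E_1)\eta_2\ddot\varepsilon}
#'
#' with time constants `tau1 = eta1/E1` (the retardation time of the
#' Kelvin-Voigt arm), `tau2 = eta2/E1`, `tau3 = eta2/E2` and
#' `kappa1 = tau1 + tau2 + tau3`. The time constants are always recomputed
#' from the four coefficients, never stored.
#'
#' @param E1 Kelvin-Voigt spring modulus, Pa.
#' @param E2 Maxwell spring modulus (instantaneous response), Pa.
#' @param eta1 Kelvin-Voigt dashpot viscosity, Pa s.
#' @param eta2 Maxwell dashpot viscosity (terminal flow), Pa s.
#' @return An object of class `burgers_params`.
#' @export
burgers_params <- function(E1, E2, eta1, eta2) {
  v <- c(E1 = E1, E2 = E2, eta1 = eta1, eta2 = eta2)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("all Burgers coefficients must be finite and strictly positive")
  structure(as.list(v), class = "burgers_params")
}

#' Derived Burgers time constants
#'
#' @param params a [burgers_params()] object.
#' @return Named vector `tau1`, `tau2`, `tau3`, `kappa1` (seconds), computed
#'   fresh from the coefficients.
#' @export
burgers_times <- function(params) {
  stopifnot(inherits(params, "burgers_params"))
  tau1 <- params$eta1 / params$E1
  tau2 <- params$eta2 / params$E1
  tau3 <- params$eta2 / params$E2
  c(tau1 = tau1, tau2 = tau2, tau3 = tau3, kappa1 = tau1 + tau2 + tau3)
}

#' @export
print.burgers_params <- function(x, ...) {
  tc <- burgers_times(x)
  cat("Burgers model parameters\n")
  cat(sprintf("  E1 = %.4g Pa, E2 = %.4g Pa\n", x$E1, x$E2))
  cat(sprintf("  eta1 = %.4g Pa s, eta2 = %.4g Pa s\n", x$eta1, x$eta2))
  cat(sprintf("  tau1 = %.4g s, tau2 = %.4g s, tau3 = %.4g s, kappa1 = %.4g s\n",
              tc["tau1"], tc["tau2"], tc["tau3"], tc["kappa1"]))
  invisible(x)
}

#' Creep compliance of the Burgers model
#'
#' `J(t) = 1/E2 + t/eta2 + (1 - exp(-t E1/eta1))/E1`: an instantaneous
#' elastic jump from the Maxwell spring, steady terminal flow from the
#' Maxwell dashpot, and a delayed (retarded) elastic contribution from the
#' Kelvin-Voigt arm with retardation time `eta1/E1`.
#'
#' @param params a [burgers_params()] object.
#' @param t times in seconds (non-negative).
#' @return Compliance in 1/Pa at each `t`.
#' @export
creep_compliance <- function(params, t) {
  stopifnot(inherits(params, "burgers_params"), all(t >= 0))
  1 / params$E2 + t / params$eta2 +
    (1 - exp(-t * params$E1 / params$eta1)) / params$E1
}

#' Creep strain under a constant step stress
#'
#' Strain response `sigma0 * J(t)` of the Burgers model to a stress step of
#' amplitude `sigma0` applied at `t = 0`.
#'
#' @param params a [burgers_params()] object.
#' @param sigma0 step stress amplitude, Pa (> 0).
#' @param t times in seconds (non-negative).
#' @return Engineering strain at each `t`.
#' @export
creep_strain <- function(params, sigma0, t) {
  stopifnot(sigma0 > 0)
  sigma0 * creep_compliance(params, t)
}

# Antiderivative of J(v); used by the hereditary integral.
compliance_integral <- function(params, v) {
  tau1 <- params$eta1 / params$E1
  v / params$E2 + v^2 / (2 * params$eta2) +
    (v + tau1 * exp(-v / tau1)) / params$E1
}

#' Strain response to an arbitrary sampled stress history
#'
#' Boltzmann superposition for a linear viscoelastic material:
#' `eps(t) = sigma(t1) J(t - t1) + integral J(t - u) dsigma(u)`, with the
#' measured stress assumed piecewise linear between samples and the load
#' applied as a step to `sigma[1]` at the first sample time. The segment
#' integrals use the closed-form antiderivative of the Burgers compliance,
#' so no numerical quadrature is involved. Reduces exactly to
#' [creep_strain()] for a constant stress record.
#'
#' @param params a [burgers_params()] object.
#' @param times strictly increasing sample times, s.
#' @param stress sampled stress at `times`, Pa.
#' @return Engineering strain at each sample time.
#' @export
strain_response <- function(params, times, stress) {
  stopifnot(inherits(params, "burgers_params"),
            length(times) == length(stress))
  if (length(times) < 2) stop("at least two samples are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  slopes <- diff(stress) / diff(times)
  eps <- stress[1] * creep_compliance(params, times - times[1])
  # contribution of segment k (= [t_k, t_{k+1}]) to all later sample times
  for (k in seq_len(n - 1)) {
    if (slopes[k] == 0) next
    j <- (k + 1):n
    eps[j] <- eps[j] + slopes[k] *
      (compliance_integral(params, times[j] - times[k]) -
         compliance_integral(params, times[j] - times[k + 1]))
  }
  eps
}

#' Frequency grid container for storage/loss moduli
#'
#' @param omega angular frequencies, rad/s, strictly increasing.
#' @param storage storage modulus (E' or G'), Pa.
#' @param loss loss modulus (E'' or G''), Pa.
#' @param kind `"compressional"` (E) or `"shear"` (G).
#' @param extrapolated optional logical flag per frequency marking points
#'   below the fundamental frequency of the record that produced them.
#' @return A data.frame of class `modulus_spectrum` with columns
#'   `omega_rad_s`, `storage_Pa`, `loss_Pa`, `tan_delta`, `kind` and, when
#'   given, `extrapolated`. `tan_delta = loss/storage` where storage > 0,
#'   `NA` elsewhere.
#' @export
modulus_spectrum <- function(omega, storage, loss,
                             kind = c("compressional", "shear"),
                             extrapolated = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(omega) == length(storage), length(omega) == length(loss))
  if (any(omega <= 0)) stop("omega must be strictly positive")
  if (any(diff(omega) <= 0)) stop("omega must be strictly increasing")
  tan_delta <- ifelse(storage > 0, loss / storage, NA_real_)
  out <- data.frame(omega_rad_s = omega, storage_Pa = storage,
                    loss_Pa = loss, tan_delta = tan_delta, kind = kind)
  if (!is.null(extrapolated)) {
    stopifnot(length(extrapolated) == length(omega))
    out$extrapolated <- as.logical(extrapolated)
  }
  structure(out, class = c("modulus_spectrum", "data.frame"))
}

#' Burgers storage and loss moduli in the frequency domain
#'
#' Closed-form compressional complex modulus of the Burgers model,
#' `E*(w) = E'(w) + i E''(w)` with
#' \deqn{E'(\omega) = \eta_2\omega^2\,
#'   \frac{\tau_2+\tau_3+\tau_1^2\tau_3\omega^2}
#'        {(1-\tau_1\tau_3\omega^2)^2+(\kappa_1\omega)^2}, \qquad
#'  E''(\omega) = \eta_2\omega\,
#'   \frac{1+(\tau_1+\tau_2)\tau_1\omega^2}
#'        {(1-\tau_1\tau_3\omega^2)^2+(\kappa_1\omega)^2}.}
#'
#' This is algebraically identical to the complex ratio
#' `(i w eta2 - tau1 eta2 w^2) / (1 + i kappa1 w - tau1 tau3 w^2)` obtained
#' by Fourier-transforming the governing equation.
#'
#' @param params a [burgers_params()] object.
#' @param omega angular frequency grid, rad/s (> 0, increasing).
#' @param kind modulus kind label, see [modulus_spectrum()].
#' @return A [modulus_spectrum()].
#' @export
burgers_moduli <- function(params, omega, kind = "compressional") {
  stopifnot(inherits(params, "burgers_params"))
  if (any(omega <= 0)) stop("omega must be strictly positive")
  tc <- burgers_times(params)
  tau1 <- tc[["tau1"]]; tau2 <- tc[["tau2"]]
  tau3 <- tc[["tau3"]]; k1 <- tc[["kappa1"]]
  eta2 <- params$eta2
  den <- (1 - tau1 * tau3 * omega^2)^2 + (k1 * omega)^2
  storage <- eta2 * omega^2 * (tau2 + tau3 + tau1^2 * tau3 * omega^2) / den
  loss <- eta2 * omega * (1 + (tau1 + tau2) * tau1 * omega^2) / den
  modulus_spectrum(omega, storage, loss, kind = kind)
}

#' Loss tangent of a modulus spectrum
#'
#' `tan(delta) = loss/storage`, the ratio of energy dissipated to energy
#' stored per cycle. Frequencies with non-positive storage modulus are
#' excluded with a message.
#'
#' @param spec a [modulus_spectrum()].
#' @return data.frame with columns `omega_rad_s`, `tan_delta`.
#' @export
loss_tangent <- function(spec) {
  stopifnot(inherits(spec, "modulus_spectrum"))
  keep <- spec$storage_Pa > 0
  if (!all(keep))
    message(sum(!keep), " frequency point(s) with non-positive storage ",
            "modulus excluded from the loss tangent")
  data.frame(omega_rad_s = spec$omega_rad_s[keep],
             tan_delta = spec$loss_Pa[keep] / spec$storage_Pa[keep])
}

#' Report Burgers parameters under an element-role convention
#'
#' The governing equation assigns the instantaneous spring and terminal
#' dashpot to the Maxwell arm `(E2, eta2)` and the retarded response to the
#' Kelvin-Voigt arm `(E1, eta1)` (`as_equation`, the default). The
#' alternative `as_discussion` convention, common when `E1` is described as
#' the instantaneous modulus and `eta1` as the long-term viscosity, swaps
#' the two pairs in reporting only; the fitted model is identical. The
#' reported triple is `(eta1, E1, tau2)` with `tau2` defined as the Maxwell
#' ratio `eta2/E2` under the active convention.
#'
#' @param params a [burgers_params()] object.
#' @param role_convention `"as_equation"` or `"as_discussion"`.
#' @return Named vector `eta1`, `E1`, `tau2`.
#' @export
burgers_report <- function(params,
                           role_convention = c("as_equation", "as_discussion")) {
  role_convention <- match.arg(role_convention)
  stopifnot(inherits(params, "burgers_params"))
  if (role_convention == "as_equation")
    c(eta1 = params$eta1, E1 = params$E1, tau2 = params$eta2 / params$E2)
  else
    c(eta1 = params$eta2, E1 = params$E2, tau2 = params$eta1 / params$E1)
}

#' Write a modulus spectrum as CSV
#'
#' Columns `omega_rad_s, storage_Pa, loss_Pa, tan_delta, kind` plus
#' `extrapolated` when present.
#'
#' @param spec a [modulus_spectrum()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "modulus_spectrum"))
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("omega_rad_s", "storage_Pa", "loss_Pa")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  modulus_spectrum(df$omega_rad_s, df$storage_Pa, df$loss_Pa,
                   kind = if ("kind" %in% names(df)) df$kind[1] else "compressional",
                   extrapolated = if ("extrapolated" %in% names(df)) df$extrapolated)
}
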