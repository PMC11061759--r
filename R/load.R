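#' Coverslip load specification
#'
#' Describes the constant compressive load applied to a spheroid by a glass
#' coverslip resting on it while submerged in culture medium or buffer. The
#' net downward force is the coverslip weight minus the Archimedes (buoyancy)
#' force of the displaced fluid, `m*g - rho*V*g`, and is constant for the
#' whole experiment.
#'
#' The coverslip geometry is an instrument property and must be supplied by
#' the user. As a non-authoritative example, a square 22 x 22 x 0.15 mm glass
#' coverslip (density ~2500 kg/m^3) has volume 7.26e-8 m^3 and mass
#' 1.815e-4 kg. The default fluid density is that of PBS, 1005 kg/m^3.
#'
#' @param coverslip_mass coverslip mass in kg.
#' @param coverslip_volume coverslip volume in m^3.
#' @param fluid_density density of the surrounding fluid in kg/m^3
#'   (default 1005, PBS).
#' @param gravity gravitational acceleration in m/s^2 (default 9.81).
#' @return An object of class `load_spec`.
#' @seealso [net_load()]
#' @examples
#' spec <- load_spec(2.0e-4, 8.0e-8)
#' net_load(spec)
#' @export
load_spec <- function(coverslip_mass, coverslip_volume,
                      fluid_density = 1005, gravity = 9.81) {
  vals <- c(coverslip_mass = coverslip_mass,
            coverslip_volume = coverslip_volume,
            fluid_density = fluid_density, gravity = gravity)
  if (!all(is.finite(vals)))
    stop("all load_spec fields must be finite numbers")
  if (any(vals[c("coverslip_mass", "coverslip_volume", "gravity")] <= 0))
    stop("coverslip mass, volume and gravity must be strictly positive")
  if (fluid_density < 0)
    stop("fluid_density must be non-negative")
  spec <- structure(as.list(vals), class = "load_spec")
  net_load(spec)  # errors if buoyant
  spec
}

#' Net compressive force of a submerged coverslip
#'
#' Weight minus buoyancy: `F = m*g - rho*V*g`. A non-positive result means
#' the coverslip floats and applies no compression; this is an error.
#'
#' @param spec a [load_spec()] object.
#' @return Net force in N (strictly positive scalar).
#' @export
net_load <- function(spec) {
  stopifnot(inherits(spec, "load_spec"))
  f <- spec$gravity * (spec$coverslip_mass -
                         spec$fluid_density * spec$coverslip_volume)
  if (f <= 0)
    stop("buoyant coverslip: net load is non-positive, no compression possible")
  f
}

#' @export
print.load_spec <- function(x, ...) {
  cat("Coverslip load specification\n")
  cat(sprintf("  mass: %.4g kg, volume: %.4g m^3\n",
              x$coverslip_mass, x$coverslip_volume))
  cat(sprintf("  fluid density: %.4g kg/m^3, g: %.4g m/s^2\n",
              x$fluid_density, x$gravity))
  cat(sprintf("  net force (weight - buoyancy): %.4g N\n", net_load(x)))
  invisible(x)
}
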