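#' Per-frame morphology measurements
#'
#' A table of calibrated per-frame measurements of the spheroid's diametral
#' cross-section: time since the start of the experiment, projected area, and
#' the diameter of the circle with the same area.
#'
#' @param time times in seconds from experiment start (non-negative).
#' @param area diametral cross-section area in m^2 (strictly positive).
#' @param equiv_diameter optional equivalent diameters in m; if supplied they
#'   must satisfy `equiv_diameter = sqrt(4*area/pi)` to within floating
#'   tolerance, otherwise they are computed from `area`.
#' @return A data.frame of class `frame_measurements` with columns
#'   `time_s`, `area_m2`, `equiv_diameter_m`.
#' @export
frame_measurements <- function(time, area, equiv_diameter = NULL) {
  stopifnot(length(time) == length(area), length(time) >= 1)
  if (any(!is.finite(time)) || any(!is.finite(area)))
    stop("times and areas must be finite")
  if (any(time < 0)) stop("times must be non-negative")
  if (any(area <= 0)) stop("areas must be strictly positive")
  d <- sqrt(4 * area / pi)
  if (!is.null(equiv_diameter)) {
    if (any(abs(equiv_diameter - d) > 1e-6 * d))
      stop("equiv_diameter inconsistent with area (expected sqrt(4*area/pi))")
    d <- equiv_diameter
  }
  structure(data.frame(time_s = time, area_m2 = area, equiv_diameter_m = d),
            class = c("frame_measurements", "data.frame"))
}

check_frames <- function(frames, min_n = 2) {
  stopifnot(is.data.frame(frames),
            all(c("time_s", "area_m2", "equiv_diameter_m") %in% names(frames)))
  if (nrow(frames) < min_n)
    stop(sprintf("at least %d frames are required", min_n))
  if (any(diff(frames$time_s) <= 0))
    stop("frame times must be strictly increasing")
  invisible(frames)
}

#' Stress history from measured areas under a constant net load
#'
#' The axial stress at each frame is the constant net coverslip force divided
#' by the current diametral area, `sigma_k = F / A_k`. Because the area grows
#' as the spheroid spreads, the stress decays over the experiment even though
#' the applied force is constant.
#'
#' @param frames a [frame_measurements()] table (>= 2 frames, strictly
#'   increasing times).
#' @param spec a [load_spec()].
#' @return Numeric vector of stresses in Pa, one per frame.
#' @export
stress_series <- function(frames, spec) {
  check_frames(frames)
  if (any(frames$area_m2 <= 0)) stop("areas must be strictly positive")
  net_load(spec) / frames$area_m2
}

#' Strain history from measured diameters
#'
#' Under the volume-conserving oblate-spheroid model the axial stretch is
#' `h(t)/h0 = (D0/D(t))^2`, where `D0` is the diameter of the first frame.
#' Two conventions are offered:
#' * `as_written`: the stretch ratio `(D0/D)^2` itself, starting at 1 and
#'   decreasing under compression;
#' * `engineering` (default): `1 - (D0/D)^2`, starting at 0 and increasing,
#'   the form conventionally used for creep fitting.
#'
#' @param frames a [frame_measurements()] table.
#' @param convention `"engineering"` or `"as_written"`.
#' @return Numeric strain vector (dimensionless), one per frame.
#' @export
strain_series <- function(frames,
                          convention = c("engineering", "as_written")) {
  convention <- match.arg(convention)
  check_frames(frames)
  d <- frames$equiv_diameter_m
  if (any(d <= 0)) stop("diameters must be strictly positive")
  d0 <- d[1]
  if (any(d < d0 * (1 - 1e-12)))
    warning("some frames have diameter below the initial diameter: ",
            "a spheroid shrinking under compression is physically suspicious")
  lambda <- (d0 / d)^2
  if (convention == "as_written") lambda else 1 - lambda
}

#' Spheroid height from its diameter under volume conservation
#'
#' The compressed spheroid is modelled as an oblate spheroid with equal long
#' axes `D` and short axis `h`; conserving the initial spherical volume
#' `pi*D0^3/6 = pi*D^2*h/6` gives `h = D0^3 / D^2`.
#'
#' @param D0 initial (spherical) diameter in m.
#' @param D current diameter in m (same length or scalar).
#' @return Height `h` in m.
#' @examples
#' height_from_diameter(400e-6, 500e-6)  # 256e-6
#' @export
height_from_diameter <- function(D0, D) {
  stopifnot(all(D0 > 0), all(D > 0))
  D0^3 / D^2
}

#' Aligned stress/strain series with geometry metadata
#'
#' Combines [stress_series()] and [strain_series()] into a single sampled
#' record with per-frame diameter and height, carrying the initial geometry
#' and the strain convention as attributes.
#'
#' @param frames a [frame_measurements()] table.
#' @param spec a [load_spec()].
#' @param convention strain convention, see [strain_series()].
#' @return A data.frame of class `stress_strain` with columns `time_s`,
#'   `stress_Pa`, `strain`, `diameter_m`, `height_m` and attributes `D0`,
#'   `h0` (both equal to the first-frame diameter) and `convention`.
#' @export
stress_strain_series <- function(frames, spec,
                                 convention = c("engineering", "as_written")) {
  convention <- match.arg(convention)
  check_frames(frames)
  d0 <- frames$equiv_diameter_m[1]
  out <- data.frame(
    time_s = frames$time_s,
    stress_Pa = stress_series(frames, spec),
    strain = strain_series(frames, convention),
    diameter_m = frames$equiv_diameter_m,
    height_m = height_from_diameter(d0, frames$equiv_diameter_m)
  )
  structure(out, class = c("stress_strain", "data.frame"),
            D0 = d0, h0 = d0, convention = convention)
}

#' Convert a stress/strain series to engineering strain
#'
#' The two strain conventions are element-wise complements
#' (`engineering = 1 - as_written`); fitting and Fourier transforms expect
#' the engineering form, which starts at 0 and grows.
#'
#' @param series a `stress_strain` data.frame.
#' @return The series with engineering strain and updated attribute.
#' @export
as_engineering <- function(series) {
  stopifnot(inherits(series, "stress_strain"))
  if (identical(attr(series, "convention"), "engineering")) return(series)
  series$strain <- 1 - series$strain
  attr(series, "convention") <- "engineering"
  series
}

#' Write / read a stress-strain series as CSV
#'
#' Plain CSV with header `time_s,stress_Pa,strain,diameter_m,height_m` and
#' '.' as decimal separator. On reading, the convention is inferred from the
#' first strain value (close to 1: `as_written`; close to 0: `engineering`)
#' and `D0` from the first diameter.
#'
#' @param series a `stress_strain` data.frame.
#' @param path file path.
#' @return `write_stress_strain` returns `path` invisibly;
#'   `read_stress_strain` returns a `stress_strain` data.frame.
#' @export
write_stress_strain <- function(series, path) {
  stopifnot(inherits(series, "stress_strain"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_strain
#' @export
read_stress_strain <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "stress_Pa", "strain")
  if (!all(need %in% names(df)))
    stop("stress-strain CSV must have columns: ", paste(need, collapse = ", "))
  convention <- if (abs(df$strain[1] - 1) < abs(df$strain[1])) "as_written"
                else "engineering"
  d0 <- if ("diameter_m" %in% names(df)) df$diameter_m[1] else NA_real_
  structure(df, class = c("stress_strain", "data.frame"),
            D0 = d0, h0 = d0, convention = convention)
}
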