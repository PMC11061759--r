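#' Configuration for a synthetic compression experiment
#'
#' Bundles everything the generator needs to emulate a coverslip creep
#' experiment: the generating Burgers parameters, the load, the initial
#' spheroid diameter, the acquisition timing (default 0.5 Hz for 8 min, i.e.
#' 240 frames), the measurement noise level and the random seed.
#'
#' The default load is a light effective load (net ~3.9e-5 N, ~310 Pa on a
#' 400-um spheroid) chosen so that the default Burgers parameters, whose
#' moduli are in the 1e2-1e3 Pa range typical of spheroids, give a strain
#' history that stays physical over the 480-s window.
#'
#' @param params generating [burgers_params()]; default
#'   `burgers_params(E1 = 2500, E2 = 1200, eta1 = 2.67e5, eta2 = 8e5)`.
#' @param load a [load_spec()]; default `load_spec(5e-6, 1e-9)`.
#' @param D0 initial spheroid diameter, m (default 400e-6).
#' @param frame_interval s between frames (default 2, i.e. 0.5 Hz).
#' @param duration total duration, s (default 480); must be an integer
#'   multiple of `frame_interval`.
#' @param noise_cv fractional multiplicative Gaussian noise applied to the
#'   strain record and to the measured areas (default 0.02).
#' @param seed integer random seed (default 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = burgers_params(E1 = 2500, E2 = 1200,
                                                      eta1 = 2.67e5,
                                                      eta2 = 8e5),
                              load = load_spec(5e-6, 1e-9),
                              D0 = 400e-6, frame_interval = 2,
                              duration = 480, noise_cv = 0.02, seed = 1L) {
  stopifnot(inherits(params, "burgers_params"), inherits(load, "load_spec"),
            D0 > 0, frame_interval > 0, duration > 0, noise_cv >= 0)
  n <- duration / frame_interval
  if (abs(n - round(n)) > 1e-9)
    stop("duration must be an integer multiple of frame_interval")
  structure(list(params = params, load = load, D0 = D0,
                 frame_interval = frame_interval, duration = duration,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a constant-force compression experiment
#'
#' Generates a physically consistent synthetic experiment with the feedback
#' the real assay exhibits: the coverslip force is constant, but as the
#' spheroid spreads its diametral area grows, so the contact stress decays.
#' Explicit time stepping per frame:
#'
#' 1. stress at the current frame = net force / previous-frame area;
#' 2. the strain state is advanced over one frame interval under the
#'    Burgers model, holding the stress constant within the step (the
#'    Kelvin-Voigt state uses its exact exponential update, so the only
#'    discretisation error is the one-step stress lag);
#' 3. diameter and area follow from the axial stretch via volume
#'    conservation, `D = D0 / sqrt(lambda)` with `lambda = 1 - strain`.
#'
#' The first frame (t = 0) is the undeformed reference. Multiplicative
#' Gaussian noise (`noise_cv`) is applied after the dynamics, independently
#' to the measured areas and to the returned strain record. The run aborts
#' if the stretch `lambda` leaves `(0, 1]` (unphysical parameter/load
#' combination). Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @param convention strain convention for the returned series.
#' @return A list with `series` (a `stress_strain` data.frame built from
#'   the noisy measurements), `frames` (a [frame_measurements()] table),
#'   and `truth` (noiseless strain, stress, diameters and the generating
#'   parameters).
#' @export
simulate_compression <- function(config,
                                 convention = c("engineering", "as_written")) {
  convention <- match.arg(convention)
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  f <- net_load(config$load)
  dt <- config$frame_interval
  n <- as.integer(round(config$duration / dt))
  times <- (seq_len(n) - 1) * dt
  tau1 <- p$eta1 / p$E1

  area <- numeric(n); stress <- numeric(n); eps <- numeric(n)
  area0 <- pi * config$D0^2 / 4
  area[1] <- area0
  stress[1] <- f / area0
  eps[1] <- 0                      # undeformed reference frame
  # instantaneous elastic jump at t = 0+, solved self-consistently with the
  # area feedback: eps = sigma/E2 with sigma = F (1 - eps)/A0, so
  # eps = c/(1 + c) where c = F/(A0 E2). Without this the explicit scheme
  # rings over the first few frames.
  cjump <- f / (area0 * p$E2)
  cur <- cjump / (1 + cjump)
  eK <- 0; eD <- 0                 # Kelvin-Voigt and Maxwell-dashpot states
  for (k in seq_len(n - 1)) {
    sig <- f * (1 - cur) / area0   # explicit: stress from current-state area
    # exact one-step update under constant stress sig
    eD <- eD + sig * dt / p$eta2
    eK <- sig / p$E1 + (eK - sig / p$E1) * exp(-dt / tau1)
    cur <- sig / p$E2 + eD + eK
    lambda <- 1 - cur
    if (lambda <= 0 || lambda > 1)
      stop("unphysical parameter/load combination: stretch left (0, 1]")
    eps[k + 1] <- cur
    area[k + 1] <- area0 / lambda
    stress[k + 1] <- f / area[k + 1]
  }
  diam <- config$D0 / sqrt(1 - eps)

  withr::with_seed(config$seed, {
    area_meas <- area * (1 + stats::rnorm(n, 0, config$noise_cv))
    eps_noise <- 1 + stats::rnorm(n, 0, config$noise_cv)
  })
  frames <- frame_measurements(times, area_meas)
  series <- stress_strain_series(frames, config$load, convention = convention)
  # direct multiplicative noise on the strain record (reference stays 0)
  eps_meas <- eps * eps_noise
  series$strain <- if (convention == "engineering") eps_meas else 1 - eps_meas
  list(series = series, frames = frames,
       truth = list(params = p, times = times, strain = eps,
                    stress = stress, diameters = diam, net_force = f))
}

#' Render a synthetic phase-contrast-like image stack
#'
#' Renders, per scheduled diameter, an anti-aliased dark disc on a bright
#' background, applies an optional Gaussian blur, and adds Gaussian pixel
#' noise. The ground-truth schedule is returned alongside the frames so
#' segmentation accuracy can be scored. Deterministic given the seed.
#'
#' @param diameters schedule of spheroid diameters, m.
#' @param pixel_size pixel calibration, m/px.
#' @param image_shape frame dimensions in pixels, `c(rows, cols)`
#'   (default `c(160, 160)`).
#' @param background_level,object_level background and disc intensities in
#'   `[0, 1]` (defaults 0.8 and 0.25; the disc is darker).
#' @param blur_sigma Gaussian blur sigma in pixels (default 1; 0 disables).
#' @param noise_sd additive Gaussian noise standard deviation
#'   (default 0.05).
#' @param seed integer random seed (default 1).
#' @return List with `frames` (list of numeric matrices) and `truth`
#'   (data.frame of scheduled `diameter_m` and `diameter_px`).
#' @export
render_stack <- function(diameters, pixel_size, image_shape = c(160, 160),
                         background_level = 0.8, object_level = 0.25,
                         blur_sigma = 1, noise_sd = 0.05, seed = 1L) {
  stopifnot(all(diameters > 0), pixel_size > 0, length(image_shape) == 2)
  radii_px <- diameters / (2 * pixel_size)
  if (any(radii_px + 10 > min(image_shape) / 2))
    stop("scheduled disk exceeds the frame (need >= 10 px margin)")
  nr <- image_shape[1]; nc <- image_shape[2]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  dist <- sqrt(outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, "+"))
  render_one <- function(r_px) {
    # coverage ramps linearly across the 1-px anti-aliased edge
    cov <- pmin(pmax(r_px + 0.5 - dist, 0), 1)
    img <- background_level + (object_level - background_level) * cov
    if (blur_sigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = blur_sigma))
    img
  }
  frames <- lapply(radii_px, render_one)
  if (noise_sd > 0) {
    frames <- withr::with_seed(seed, lapply(frames, function(img)
      img + matrix(stats::rnorm(length(img), 0, noise_sd),
                   nrow(img), ncol(img))))
  }
  list(frames = frames,
       truth = data.frame(diameter_m = diameters, diameter_px = 2 * radii_px))
}

#' Parameter-recovery study on synthetic constant-stress creep
#'
#' Repeatedly generates a Burgers creep record at the study's acquisition
#' settings (by default 240 samples at 0.5 Hz), corrupts the strain with
#' multiplicative Gaussian noise, fits the Burgers model back with
#' [fit_burgers()], and tabulates the recovered coefficients. Used to
#' quantify how well the acquisition protocol constrains each parameter.
#'
#' @param params generating [burgers_params()].
#' @param sigma0 constant stress amplitude, Pa (default 300).
#' @param n_reps number of replicates (default 20).
#' @param noise_cv multiplicative strain noise level (default 0.02).
#' @param frame_interval,duration acquisition timing, s (defaults 2 and
#'   480).
#' @param seeds integer seeds, one per replicate; default `base_seed + 1:n`.
#' @param base_seed offset for the default seeds (default 0).
#' @param mode fitting mode, see [fit_burgers()].
#' @return data.frame with one row per replicate (`seed`, recovered `E1`,
#'   `E2`, `eta1`, `eta2`, `residual_norm`) and the generating parameters in
#'   the `truth` attribute.
#' @export
recover_parameters <- function(params, sigma0 = 300, n_reps = 20,
                               noise_cv = 0.02, frame_interval = 2,
                               duration = 480, seeds = NULL, base_seed = 0,
                               mode = "constant_stress") {
  stopifnot(inherits(params, "burgers_params"))
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_reps)
  stopifnot(length(seeds) == n_reps)
  t <- seq(0, duration - frame_interval, by = frame_interval)
  eps_true <- creep_strain(params, sigma0, t)
  rows <- lapply(seq_len(n_reps), function(i) {
    eps <- withr::with_seed(seeds[i],
      eps_true * (1 + stats::rnorm(length(t), 0, noise_cv)))
    series <- data.frame(time_s = t, stress_Pa = sigma0, strain = eps)
    fit <- fit_burgers(series, mode = mode)
    data.frame(seed = seeds[i], E1 = fit$params$E1, E2 = fit$params$E2,
               eta1 = fit$params$eta1, eta2 = fit$params$eta2,
               residual_norm = fit$residual_norm)
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- params
  out
}
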