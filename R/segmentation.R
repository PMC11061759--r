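#' Segment a spheroid in a single grayscale frame
#'
#' Detects the spheroid's diametral cross-section as the largest dark
#' connected object in a phase-contrast-like frame. The pipeline is:
#' optional polynomial background flattening, intensity inversion (spheroids
#' are dark on a bright background), Otsu global threshold, hole filling,
#' morphological opening with a disc structuring element, and selection of
#' the largest connected component (8-connectivity). Each step can be
#' toggled. The result is deterministic and invariant to adding a constant
#' to all pixel intensities.
#'
#' @param image 2-D numeric matrix (grayscale, any intensity scale), at
#'   least 64 x 64 pixels, finite values.
#' @param min_area_px minimum acceptable object area in pixels; if the
#'   largest component is smaller, an error `"no spheroid found"` is raised.
#' @param dark_object `TRUE` (default) when the spheroid is darker than the
#'   background; `FALSE` for bright objects.
#' @param flatten_background subtract a second-order polynomial illumination
#'   surface before thresholding (default `TRUE`).
#' @param fill_holes fill interior holes of the thresholded object
#'   (default `TRUE`).
#' @param opening_radius radius in pixels of the disc used for morphological
#'   opening; 0 disables opening (default 2).
#' @return A list of class `segmentation_result`: `mask` (logical matrix
#'   with exactly one connected foreground component), `area_px`,
#'   `centroid` (row, col), `equiv_diameter_px = sqrt(4*area_px/pi)` and
#'   `qc_flags` (character vector; may contain `"touching_border"` and
#'   `"low_contrast"`).
#' @export
segment_spheroid <- function(image, min_area_px = 64, dark_object = TRUE,
                             flatten_background = TRUE, fill_holes = TRUE,
                             opening_radius = 2) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (any(dim(image) < 64)) stop("image must be at least 64 x 64 pixels")
  if (!all(is.finite(image))) stop("image must contain only finite values")
  rng <- range(image)
  if (diff(rng) <= 0) stop("no spheroid found: image has no contrast")
  x <- (image - rng[1]) / diff(rng)
  if (dark_object) x <- 1 - x
  if (flatten_background) x <- flatten_poly2(x)
  th <- EBImage::otsu(EBImage::Image(x), range = range(x))
  mask <- x > th
  low_contrast <- mean(x[mask]) - mean(x[!mask]) < 0.15
  m <- EBImage::Image(mask * 1)
  if (fill_holes) m <- EBImage::fillHull(m)
  if (opening_radius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2 * opening_radius + 1, "disc"))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (max(lab) == 0) stop("no spheroid found")
  areas <- tabulate(lab[lab > 0])
  biggest <- which.max(areas)
  if (areas[biggest] < min_area_px) stop("no spheroid found")
  mask <- lab == biggest
  area_px <- areas[biggest]
  idx <- which(mask, arr.ind = TRUE)
  qc <- character(0)
  if (any(idx[, 1] %in% c(1, nrow(mask))) || any(idx[, 2] %in% c(1, ncol(mask))))
    qc <- c(qc, "touching_border")
  if (low_contrast) qc <- c(qc, "low_contrast")
  structure(list(mask = mask, area_px = area_px,
                 centroid = colMeans(idx),
                 equiv_diameter_px = sqrt(4 * area_px / pi),
                 qc_flags = qc),
            class = "segmentation_result")
}

# Subtract a 2nd-order polynomial illumination surface fitted to a coarse
# pixel subsample (robust enough for slowly varying backgrounds).
flatten_poly2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- seq(1, nr, length.out = min(nr, 32))
  ci <- seq(1, nc, length.out = min(nc, 32))
  grid <- expand.grid(r = ri, c = ci)
  z <- x[cbind(round(grid$r), round(grid$c))]
  X <- cbind(1, grid$r, grid$c, grid$r^2, grid$c^2, grid$r * grid$c)
  # median-like robustness: two reweighted passes against the object pixels
  fit <- stats::lm.fit(X, z)
  for (i in 1:2) {
    w <- as.numeric(abs(fit$residuals) <= 2 * stats::mad(fit$residuals) + 1e-12)
    fit <- stats::lm.fit(X * sqrt(w), z * sqrt(w))
  }
  b <- fit$coefficients
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  bg <- b[1] + b[2] * rr + b[3] * cc + b[4] * rr^2 + b[5] * cc^2 + b[6] * rr * cc
  x - bg + mean(bg)
}

#' Measure a time-lapse stack of spheroid frames
#'
#' Runs [segment_spheroid()] on every frame and converts pixel measurements
#' to calibrated units: `time = (index - 1) * frame_interval`,
#' `area = area_px * pixel_size^2`, equivalent diameter from the area.
#' Frames where segmentation fails are gap-filled by linear interpolation of
#' the area across at most `max_gap` consecutive failures (longer gaps, or
#' more than 20% failed frames overall, abort with an error). Interpolated
#' frames are recorded in the `interpolated` attribute and reported with a
#' message.
#'
#' @param images list of 2-D numeric matrices (ordered frames), or a 3-D
#'   array with frames along the third dimension.
#' @param pixel_size pixel calibration, m/px (> 0).
#' @param frame_interval time between frames, s (> 0).
#' @param min_area_px passed to [segment_spheroid()].
#' @param max_gap maximum run of consecutive failed frames that may be
#'   interpolated (default 3).
#' @param ... further arguments passed to [segment_spheroid()].
#' @return A [frame_measurements()] table with attributes `interpolated`
#'   (logical per frame) and `qc_flags` (list of per-frame flag vectors).
#' @export
measure_stack <- function(images, pixel_size, frame_interval,
                          min_area_px = 64, max_gap = 3, ...) {
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  stopifnot(is.list(images), length(images) >= 2,
            pixel_size > 0, frame_interval > 0)
  n <- length(images)
  area_px <- rep(NA_real_, n)
  qc <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(segment_spheroid(images[[i]], min_area_px = min_area_px, ...),
                    error = function(e) NULL)
    if (!is.null(res)) {
      area_px[i] <- res$area_px
      qc[[i]] <- res$qc_flags
    }
  }
  failed <- is.na(area_px)
  if (mean(failed) > 0.2)
    stop(sprintf("segmentation failed on %d of %d frames (> 20%%): aborting",
                 sum(failed), n))
  if (any(failed)) {
    runs <- rle(failed)
    if (any(runs$lengths[runs$values] > max_gap))
      stop(sprintf("more than %d consecutive frames failed segmentation",
                   max_gap))
    area_px <- stats::approx(which(!failed), area_px[!failed],
                             xout = seq_len(n), rule = 2)$y
    message(sum(failed), " failed frame(s) gap-filled by linear interpolation")
  }
  out <- frame_measurements(time = (seq_len(n) - 1) * frame_interval,
                            area = area_px * pixel_size^2)
  attr(out, "interpolated") <- failed
  attr(out, "qc_flags") <- qc
  out
}

#' Read a grayscale image stack
#'
#' Accepts a multi-page TIFF file or a directory of single-frame PNG/TIFF
#' files (sorted lexicographically). 8- and 16-bit grayscale images are
#' returned as numeric matrices in `[0, 1]`; RGB frames are averaged across
#' channels.
#'
#' @param path TIFF file or directory path.
#' @return List of 2-D numeric matrices.
#' @export
read_image_stack <- function(path) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                          drop = FALSE], c(1, 2), mean)
    matrix(as.numeric(a), nrow = dim(a)[1])
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) to_gray(png::readPNG(f))
      else to_gray(tiff::readTIFF(f))
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, to_gray)
  } else stop("input path does not exist: ", path)
}

#' Write segmentation masks as a multi-page TIFF
#'
#' Quality-control export: each page is a binary mask (0 background,
#' 1 object).
#'
#' @param masks list of logical matrices.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(masks, path) {
  stopifnot(is.list(masks))
  tiff::writeTIFF(lapply(masks, function(m) matrix(as.numeric(m), nrow(m))),
                  path)
  invisible(path)
}
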