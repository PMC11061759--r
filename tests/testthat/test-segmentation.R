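test_that("a rendered dark disk is segmented to within 2 px of truth", {
  st <- render_stack(rep(200e-6, 1), pixel_size = 1e-6,
                     image_shape = c(256, 256), noise_sd = 0.055, seed = 3)
  res <- segment_spheroid(st$frames[[1]])
  expect_s3_class(res, "segmentation_result")
  expect_lt(abs(res$equiv_diameter_px - 200), 2)
  expect_equal(res$equiv_diameter_px, sqrt(4 * res$area_px / pi))
  expect_equal(unname(res$centroid), c(128.5, 128.5), tolerance = 0.02)
  expect_length(res$qc_flags, 0)
  # mask has exactly one connected component
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(res$mask * 1)))
  expect_equal(max(lab), 1)
})

test_that("degenerate and multi-object inputs follow the documented rules", {
  # uniform blank image: nothing to segment
  expect_error(segment_spheroid(matrix(0.5, 128, 128)), "no spheroid found")
  # largest of two disks wins
  img <- matrix(0.9, 300, 300)
  centres <- list(c(110, 110, 100), c(250, 250, 30))
  for (cc in centres) {
    rr <- sqrt(outer((seq_len(300) - cc[1])^2, (seq_len(300) - cc[2])^2, "+"))
    img[rr <= cc[3]] <- 0.2
  }
  res <- segment_spheroid(img)
  expect_lt(abs(res$equiv_diameter_px - 200), 2)
  expect_equal(unname(res$centroid), c(110, 110), tolerance = 0.02)
  # min_area_px above the largest object: no spheroid found
  expect_error(segment_spheroid(img, min_area_px = 1e5), "no spheroid found")
  # object touching the border is returned but flagged
  img2 <- matrix(0.9, 128, 128)
  rr <- sqrt(outer((seq_len(128) - 1)^2, (seq_len(128) - 64)^2, "+"))
  img2[rr <= 40] <- 0.2
  expect_true("touching_border" %in% segment_spheroid(img2)$qc_flags)
  expect_error(segment_spheroid(matrix(0.5, 32, 32)), "64 x 64")
})

test_that("segmentation is idempotent and intensity-shift invariant", {
  st <- render_stack(rep(180e-6, 1), pixel_size = 1.5e-6,
                     image_shape = c(160, 160), noise_sd = 0.05, seed = 9)
  img <- st$frames[[1]]
  a <- segment_spheroid(img)
  b <- segment_spheroid(img)            # determinism
  expect_identical(a$mask, b$mask)
  shifted <- segment_spheroid(img + 17.3)  # adding a constant changes nothing
  expect_identical(a$mask, shifted$mask)
})

test_that("equivalent diameter is rotation invariant for an ellipse", {
  render_ellipse <- function(theta) {
    img <- matrix(0.9, 200, 200)
    x <- outer(seq_len(200) - 100.5, rep(1, 200))
    y <- outer(rep(1, 200), seq_len(200) - 100.5)
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    img[(xr / 60)^2 + (yr / 40)^2 <= 1] <- 0.2
    img
  }
  d0 <- segment_spheroid(render_ellipse(0))$equiv_diameter_px
  d30 <- segment_spheroid(render_ellipse(pi / 6))$equiv_diameter_px
  d90 <- segment_spheroid(render_ellipse(pi / 2))$equiv_diameter_px
  expect_equal(d0, 2 * sqrt(60 * 40), tolerance = 0.01)
  expect_lt(abs(d30 - d0), 2)
  expect_lt(abs(d90 - d0), 2)
})

test_that("stack measurement calibrates, gap-fills and aborts as specified", {
  sched <- seq(180e-6, 230e-6, length.out = 10)
  st <- render_stack(sched, pixel_size = 2.5e-6, image_shape = c(160, 160),
                     noise_sd = 0.05, seed = 21)
  fm <- measure_stack(st$frames, pixel_size = 2.5e-6, frame_interval = 2)
  expect_equal(fm$time_s, 2 * (0:9))
  expect_lt(max(abs(fm$equiv_diameter_m / sched - 1)), 0.01)
  # identical frames give identical measurements
  fm2 <- measure_stack(rep(st$frames[1], 4), pixel_size = 2.5e-6,
                       frame_interval = 2)
  expect_equal(length(unique(fm2$area_m2)), 1)
  # pixel-area arithmetic: 31416 px^2 at 1 um/px -> 3.1416e-8 m^2, D ~ 200 um
  img <- matrix(0.9, 256, 256)
  rr <- sqrt(outer((seq_len(256) - 128.5)^2, (seq_len(256) - 128.5)^2, "+"))
  img[rr <= 100] <- 0.2
  one <- measure_stack(list(img, img), pixel_size = 1e-6, frame_interval = 2)
  expect_equal(one$area_m2[1], 31416e-12, tolerance = 5e-3)
  expect_equal(one$equiv_diameter_m[1], 2.0e-4, tolerance = 5e-3)
  # a short run of blank frames is interpolated and logged
  blank <- matrix(0.5, 160, 160)
  frames_gap <- st$frames
  frames_gap[[4]] <- blank
  expect_message(fmg <- measure_stack(frames_gap, 2.5e-6, 2), "gap-filled")
  expect_true(attr(fmg, "interpolated")[4])
  expect_equal(fmg$area_m2[4], (fmg$area_m2[3] + fmg$area_m2[5]) / 2,
               tolerance = 1e-9)
  # too many failures abort
  frames_bad <- st$frames
  for (i in c(2, 4, 6)) frames_bad[[i]] <- blank
  expect_error(measure_stack(frames_bad, 2.5e-6, 2), "20%")
})

test_that("image stacks round-trip through TIFF and PNG on disk", {
  st <- render_stack(c(180e-6, 200e-6, 220e-6), pixel_size = 2.5e-6,
                     noise_sd = 0.03, seed = 4)
  clipped <- lapply(st$frames, function(f) pmin(pmax(f, 0), 1))
  tdir <- withr::local_tempdir()
  tpath <- file.path(tdir, "stack.tiff")
  tiff::writeTIFF(clipped, tpath, bits.per.sample = 16)
  back <- read_image_stack(tpath)
  expect_length(back, 3)
  expect_equal(back[[2]], clipped[[2]], tolerance = 1e-4)
  pdir <- file.path(tdir, "frames")
  dir.create(pdir)
  for (i in 1:3)
    png::writePNG(clipped[[i]], file.path(pdir, sprintf("f%03d.png", i)))
  back2 <- read_image_stack(pdir)
  expect_length(back2, 3)
  expect_equal(back2[[1]], clipped[[1]], tolerance = 1e-2)
  # mask QC export
  masks <- lapply(back, function(f) f < 0.5)
  mpath <- file.path(tdir, "masks.tiff")
  write_mask_stack(masks, mpath)
  expect_true(file.exists(mpath))
})
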