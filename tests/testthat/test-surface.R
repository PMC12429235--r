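test_that("circular tube radius is recovered to sub-voxel accuracy", {
  ph <- phantom_straight()
  surf <- radial_sample(segment_of(ph))
  expect_lt(max(abs(surf$r_total - 9)), 0.5 * 0.6)
})

test_that("elliptical boundary follows the polar ellipse formula", {
  ph <- make_tube_mask(tube_spec(base_radius = 9, length = 40,
    cross_section_ratio = 0.75
  ))
  surf <- radial_sample(crop_trachea(ph$mask, z_carina = 1L))
  th <- surf$theta_grid
  a <- 9 * sqrt(0.75)
  b <- 9 / sqrt(0.75)
  r_true <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  expect_lt(max(abs(sweep(surf$r_total, 1, r_true))), 0.5 * 0.6)
})

test_that("a sinusoidal wall perturbation lands in the shape component", {
  ph <- make_tube_mask(tube_spec(base_radius = 9, length = 60,
    perturbation = list(kind = "sinusoid", amplitude = 1, n_theta_cycles = 6,
      n_z_cycles = 0
    )
  ))
  surf <- decompose(radial_sample(crop_trachea(ph$mask, z_carina = 1L)))
  # amplitude of the 6-cycle harmonic of r_shape, per slice
  amp6 <- apply(surf$r_shape, 2, function(v) 2 * Mod(fft(v)[7]) / length(v))
  expect_equal(mean(amp6), 1, tolerance = 0.2)
})

test_that("the decomposition is additive to machine precision", {
  for (ph in list(phantom_bowed(), phantom_textured())) {
    surf <- decompose(radial_sample(segment_of(ph)))
    recon <- matrix(surf$mean_radius, nrow(surf$r_total), ncol(surf$r_total),
      byrow = TRUE
    ) + surf$r_curvature + surf$r_shape
    expect_lt(max(abs(surf$r_total - recon)), 1e-12)
  }
})

test_that("bowed tubes are curvature-dominated, textured tubes shape-dominated", {
  surf_b <- decompose(radial_sample(segment_of(phantom_bowed())))
  rms <- function(m) sqrt(mean(m^2))
  expect_lt(rms(surf_b$r_shape), 0.2 * rms(surf_b$r_curvature))
  surf_t <- suppressWarnings(
    decompose(radial_sample(segment_of(phantom_textured())))
  )
  expect_lt(rms(surf_t$r_curvature), 0.2 * rms(surf_t$r_shape))
})

test_that("straight circular tubes have near-zero shape and curvature", {
  surf <- decompose(radial_sample(segment_of(phantom_straight())))
  expect_lt(max(abs(surf$r_shape)), 0.5 * 0.6)
  expect_lt(max(abs(surf$r_curvature)), 0.5 * 0.6)
})

test_that("in-plane 90-degree rotation permutes theta columns and leaves SR alone", {
  ph <- phantom_textured()
  seg <- segment_of(ph)
  surf <- suppressWarnings(decompose(radial_sample(seg)))
  sr <- fractal_estimate(to_heightmap(surf, "shape"))$SR

  arr <- seg$mask$data
  d <- dim(arr)
  rot <- aperm(arr, c(2, 1, 3))[, d[1]:1, ] # maps theta to theta + 90 deg
  seg_r <- crop_trachea(
    voxel_mask(rot, seg$mask$spacing[c(2, 1, 3)]),
    z_carina = seg$z_carina, top_offset_mm = 0
  )
  surf_r <- suppressWarnings(decompose(radial_sample(seg_r)))
  # rotated frame samples angle phi where the original had phi + 90 deg
  n <- length(surf$theta_grid)
  n4 <- n / 4
  idx <- ((seq_len(n) - 1 - n4) %% n) + 1
  shifted <- surf_r$r_total[idx, ]
  expect_lt(median(abs(shifted - surf$r_total)), 0.15)
  sr_r <- fractal_estimate(to_heightmap(surf_r, "shape"))$SR
  expect_lt(abs(sr_r - sr), 2)
})

test_that("doubling the angular sampling barely moves SR", {
  ph <- phantom_textured()
  seg <- segment_of(ph)
  sr <- vapply(c(180L, 360L), function(nt) {
    surf <- suppressWarnings(decompose(radial_sample(seg, n_theta = nt)))
    fractal_estimate(to_heightmap(surf, "shape"))$SR
  }, numeric(1))
  expect_lt(abs(sr[2] - sr[1]), 2)
})

test_that("unrolled renders are written with a mm-per-gray sidecar", {
  ph <- phantom_textured()
  surf <- suppressWarnings(decompose(radial_sample(segment_of(ph))))
  f <- withr::local_tempfile(fileext = ".png")
  render_unrolled(surf, "shape", f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".txt")))
  expect_match(readLines(paste0(f, ".txt")), "mm_per_gray", all = FALSE)
  img_s <- png::readPNG(f)
  render_unrolled(surf, "curvature", f)
  expect_gt(max(abs(png::readPNG(f) - img_s)), 0) # components differ

  # constant surface renders as uniform gray
  flat <- surf
  flat$r_total <- matrix(9, nrow(surf$r_total), ncol(surf$r_total))
  f2 <- withr::local_tempfile(fileext = ".png")
  render_unrolled(flat, "total", f2)
  expect_equal(sd(png::readPNG(f2)), 0)
})

test_that("a localized bump renders as a bright blob at its location", {
  ph <- phantom_straight()
  surf <- radial_sample(segment_of(ph))
  nt <- length(surf$theta_grid)
  nz <- length(surf$z_grid)
  bump <- outer(
    exp(-((seq_len(nt) - 90)^2) / 50),
    exp(-((seq_len(nz) - 20)^2) / 20)
  )
  surf$r_total <- surf$r_total + 3 * bump
  f <- withr::local_tempfile(fileext = ".png")
  render_unrolled(surf, "total", f)
  img <- png::readPNG(f) # rows = z reversed, cols = theta
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[2] - 90), 5)
  expect_lt(abs((nz - peak[1] + 1) - 20), 5)
})

test_that("tidy() of a surface returns the long radius table", {
  ph <- phantom_straight()
  surf <- decompose(radial_sample(segment_of(ph)))
  tb <- tidy(surf)
  expect_s3_class(tb, "tbl_df")
  expect_identical(nrow(tb), length(surf$theta_grid) * length(surf$z_grid))
  expect_named(tb, c("theta", "z_mm", "r_total", "r_shape", "r_curvature"))
  expect_s3_class(autoplot(surf, "shape"), "ggplot")
})
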