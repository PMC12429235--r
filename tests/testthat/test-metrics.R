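test_that("tracheal index of a circular tube is 1 within voxelization", {
  ph <- phantom_circular()
  seg <- segment_of(ph)
  ti <- tracheal_index(seg)
  expect_equal(ti$TI, 1, tolerance = 0.05)
  ti2 <- tracheal_index(seg, surface = radial_sample(seg))
  expect_equal(ti2$TI, 1, tolerance = 0.05)
})

test_that("tracheal index recovers a constructed elliptical ratio", {
  ph <- phantom_elliptical()
  seg <- segment_of(ph)
  ti <- tracheal_index(seg, surface = radial_sample(seg))
  expect_equal(ti$TI, 0.75, tolerance = 0.05)
})

test_that("the TI window ends 2 cm above the carina", {
  # ratio narrows toward the carina: the in-window minimum must sit at the
  # inferior window edge, excluding the narrower slices below it
  ph <- make_tube_mask(tube_spec(base_radius = 9, length = 100,
    cross_section_ratio = c(0.7, 1.0) # 0.7 inferior, 1.0 superior
  ))
  seg <- crop_trachea(ph$mask, z_carina = 1L)
  ti <- tracheal_index(seg)
  window_lo <- seg$z_carina + 20L # 1 mm slices
  expect_lte(abs(ti$TI_slice - window_lo), 1L)
  truth_ratio <- ph$truth$per_slice$ratio[ti$TI_slice]
  expect_equal(ti$TI, truth_ratio, tolerance = 0.05)
  # reported TI is the minimum of the emitted in-window table, exactly
  win <- ti$per_slice[ti$per_slice$in_window, ]
  expect_identical(ti$TI, min(win$ratio))
})

test_that("empty TI windows are rejected", {
  ph <- phantom_straight()
  seg <- crop_trachea(ph$mask, z_carina = 1L)
  expect_error(tracheal_index(seg, window = c(50L, 40L)),
    class = "tracheasr_window_error"
  )
  expect_error(tracheal_index(seg, ti_window_mm = 500),
    class = "tracheasr_window_error"
  )
})

test_that("LAA-950 counts strictly sub-threshold lung voxels", {
  dims <- c(20, 20, 10)
  lung <- voxel_mask(array(1L, dims), c(1, 1, 1))
  ct <- ct_volume(array(-900, dims), c(1, 1, 1))
  expect_identical(laa950(ct, lung), 0)

  hu <- array(-900, dims)
  hu[, , 1] <- -980 # exactly 10% of voxels
  expect_equal(laa950(ct_volume(hu, c(1, 1, 1)), lung), 10)

  hu[, , 1] <- -950 # boundary value must not count
  expect_identical(laa950(ct_volume(hu, c(1, 1, 1)), lung), 0)

  expect_error(
    laa950(ct_volume(array(-900, c(5, 5, 5)), c(1, 1, 1)), lung),
    class = "tracheasr_pairing_error"
  )
  expect_error(
    laa950(ct, voxel_mask(array(0L, dims), c(1, 1, 1))),
    class = "tracheasr_degenerate_input_error"
  )
})

test_that("the full pipeline is flat-limited on smooth phantoms", {
  tm <- suppressWarnings(compute_all(phantom_circular()$mask))
  expect_lt(tm$metrics$SR_S, 3)
  expect_lt(tm$metrics$SR_C, 3)
  expect_equal(tm$metrics$TI, 1, tolerance = 0.05)
})

test_that("texture raises SR_S above the smooth baseline", {
  tm_smooth <- suppressWarnings(compute_all(phantom_circular()$mask))
  tm_rough <- suppressWarnings(compute_all(phantom_textured()$mask))
  expect_gt(tm_rough$metrics$SR_S, tm_smooth$metrics$SR_S)
})

test_that("the pipeline is deterministic for fixed input and config", {
  ph <- phantom_textured()
  tm1 <- suppressWarnings(compute_all(ph$mask))
  tm2 <- suppressWarnings(compute_all(ph$mask))
  expect_identical(glance(tm1), glance(tm2))
  expect_identical(tidy(tm1), tidy(tm2))
})

test_that("config hashes track parameter changes into the output", {
  c1 <- sr_config()
  c2 <- sr_config(smoothing_span_mm = 10)
  expect_false(identical(c1$hash, c2$hash))
  tm <- suppressWarnings(compute_all(phantom_circular()$mask, c1))
  expect_identical(tm$metrics$config_hash, c1$hash)
})

test_that("manual carina override and stage errors are surfaced", {
  ph <- phantom_straight() # no bifurcation: detection must fail
  expect_error(compute_all(ph$mask), class = "tracheasr_carina_error")
  tm <- compute_all(ph$mask, sr_config(z_carina = 1L))
  expect_s3_class(tm, "trachea_metrics")
  expect_error(
    compute_all(voxel_mask(array(0L, c(8, 8, 8)), c(1, 1, 1))),
    class = "tracheasr_carina_error"
  )
})

test_that("batches keep going past corrupt cases and are reproducible", {
  dir <- withr::local_tempdir()
  write_mask(phantom_circular()$mask, file.path(dir, "case_a.nii.gz"))
  write_mask(phantom_textured()$mask, file.path(dir, "case_b.nii.gz"))
  writeLines("not a nifti", file.path(dir, "case_c.nii"))

  csv <- file.path(dir, "metrics.csv")
  out <- run_batch(dir, output_csv = csv)
  expect_identical(nrow(out), 3L)
  expect_identical(sum(out$status == "ok"), 2L)
  expect_match(out$status[out$case_id == "case_c.nii"], "failed")
  expect_true(file.exists(csv))

  out2 <- run_batch(dir)
  expect_identical(
    out[c("case_id", "SR_S", "SR_C", "SR_T", "TI", "config_hash")],
    out2[c("case_id", "SR_S", "SR_C", "SR_T", "TI", "config_hash")]
  )
  expect_error(run_batch(file.path(dir, "missing")), class = "tracheasr_io_error")
})

test_that("SR_S orders a small batch by constructed texture amplitude", {
  amps <- c(0.5, 1, 2)
  sr <- vapply(amps, function(a) {
    ph <- make_tube_mask(tube_spec(base_radius = 9, length = 100,
      perturbation = list(kind = "fbm", H = 0.5, amplitude_rms = a, seed = 17),
      bifurcation = list(z_split = 25, branch_angle = 25)
    ))
    suppressWarnings(compute_all(ph$mask))$metrics$SR_S
  }, numeric(1))
  expect_identical(cor(amps, sr, method = "spearman"), 1)
})
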