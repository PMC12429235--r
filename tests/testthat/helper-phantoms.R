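# Phantom fixtures shared across test files. Built once per test run and
# memoised, since voxelization is the slow part.

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .phantom_cache)) {
    assign(key, force(expr), envir = .phantom_cache)
  }
  get(key, envir = .phantom_cache)
}

phantom_circular <- function() {
  cached("circular", make_tube_mask(
    tube_spec(base_radius = 9, length = 100,
      bifurcation = list(z_split = 25, branch_angle = 25)
    )
  ))
}

phantom_elliptical <- function() {
  cached("elliptical", make_tube_mask(
    tube_spec(base_radius = 9, length = 100, cross_section_ratio = 0.75,
      bifurcation = list(z_split = 25, branch_angle = 25)
    )
  ))
}

phantom_textured <- function(amplitude = 1, H = 0.5, seed = 3) {
  cached(sprintf("textured_%g_%g_%d", amplitude, H, seed), make_tube_mask(
    tube_spec(base_radius = 9, length = 100,
      perturbation = list(kind = "fbm", H = H, amplitude_rms = amplitude, seed = seed),
      bifurcation = list(z_split = 25, branch_angle = 25)
    )
  ))
}

phantom_bowed <- function() {
  cached("bowed", make_tube_mask(
    tube_spec(base_radius = 9, length = 100,
      centerline = list(kind = "bowed", amplitude = 5, wavelength = 200),
      bifurcation = list(z_split = 25, branch_angle = 25)
    )
  ))
}

# straight tube, no bifurcation: whole tube is the segment
phantom_straight <- function() {
  cached("straight", make_tube_mask(tube_spec(base_radius = 9, length = 60)))
}

segment_of <- function(ph, ...) {
  if (is.na(ph$truth$carina_slice)) {
    crop_trachea(ph$mask, z_carina = 1L, ...)
  } else {
    crop_trachea(ph$mask, z_carina = find_carina(ph$mask), ...)
  }
}
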