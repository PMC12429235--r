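# Phantom generator: voxelized tubes with elliptical cross-sections,
# optional centerline bow, fractional-Brownian or sinusoidal wall texture,
# and an optional distal bifurcation with known carina position.

#' Specify a tube phantom
#'
#' Describes a roughly vertical tubular lumen used to exercise the full
#' analysis pipeline with known ground truth. Axial position `z` runs from 0
#' (inferior end) to `length` (superior end) in mm.
#'
#' @param base_radius Tube radius in mm (default 9, a typical adult trachea).
#' @param length Tube length in mm.
#' @param centerline `list(kind = "straight")` or
#'   `list(kind = "bowed", amplitude = <mm>, wavelength = <mm>)`, a sinusoidal
#'   bow of the centerline in the x (coronal) direction.
#' @param cross_section_ratio Coronal/sagittal diameter ratio d_c/d_s.
#'   Scalar for a constant ratio, or length-2 `c(inferior, superior)` for a
#'   linear variation along z. Must lie in (0, 1.5].
#' @param perturbation Radial wall texture: `list(kind = "none")`,
#'   `list(kind = "fbm", H = <Hurst in (0,1)>, amplitude_rms = <mm>, seed = <int>)`
#'   or `list(kind = "sinusoid", amplitude = <mm>, n_theta_cycles = <int>,
#'   n_z_cycles = <int>)`.
#' @param bifurcation `NULL`, or `list(z_split = <mm from tube bottom>,
#'   branch_angle = <degrees>)`. Below `z_split` the lumen splits into two
#'   child tubes whose centres separate linearly with depth; the two children
#'   are disjoint immediately below the split, so the last single-lumen slice
#'   (the carina) sits at `z_split`.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(base_radius = 9, length = 100,
                      centerline = list(kind = "straight"),
                      cross_section_ratio = 1,
                      perturbation = list(kind = "none"),
                      bifurcation = NULL) {
  if (!is.numeric(base_radius) || base_radius <= 0) {
    abort("`base_radius` must be > 0 mm.", class = "tracheasr_argument_error")
  }
  if (!is.numeric(length) || length <= 0) {
    abort("`length` must be > 0 mm.", class = "tracheasr_argument_error")
  }
  r <- cross_section_ratio
  if (!is.numeric(r) || !(base::length(r) %in% 1:2) || any(r <= 0) || any(r > 1.5)) {
    abort("`cross_section_ratio` must be in (0, 1.5], scalar or length 2.",
      class = "tracheasr_argument_error"
    )
  }
  kind <- perturbation$kind %||% "none"
  if (kind == "fbm") {
    if (is.null(perturbation$H) || perturbation$H <= 0 || perturbation$H >= 1) {
      abort("fbm perturbation needs Hurst exponent H strictly in (0,1).",
        class = "tracheasr_argument_error"
      )
    }
    if (is.null(perturbation$amplitude_rms) || perturbation$amplitude_rms < 0) {
      abort("fbm perturbation needs amplitude_rms >= 0 (mm).",
        class = "tracheasr_argument_error"
      )
    }
    perturbation$seed <- as.integer(perturbation$seed %||% 1L)
  } else if (kind == "sinusoid") {
    if (is.null(perturbation$amplitude) || perturbation$amplitude < 0) {
      abort("sinusoid perturbation needs amplitude >= 0 (mm).",
        class = "tracheasr_argument_error"
      )
    }
    perturbation$n_theta_cycles <- perturbation$n_theta_cycles %||% 6
    perturbation$n_z_cycles <- perturbation$n_z_cycles %||% 0
  } else if (kind != "none") {
    abort(sprintf("Unknown perturbation kind '%s'.", kind),
      class = "tracheasr_argument_error"
    )
  }
  if (!is.null(bifurcation)) {
    if (is.null(bifurcation$z_split) || bifurcation$z_split <= 0 ||
      bifurcation$z_split >= length) {
      abort("`bifurcation$z_split` must lie strictly inside (0, length).",
        class = "tracheasr_argument_error"
      )
    }
    bifurcation$branch_angle <- bifurcation$branch_angle %||% 25
    bifurcation$child_radius_frac <- bifurcation$child_radius_frac %||% 0.6
  }
  structure(
    list(
      base_radius = base_radius, length = length, centerline = centerline,
      cross_section_ratio = r, perturbation = perturbation,
      bifurcation = bifurcation
    ),
    class = "tube_spec"
  )
}

# centerline x-offset (mm) at tube-local axial position z (mm)
centerline_offset <- function(centerline, z) {
  if (identical(centerline$kind, "bowed")) {
    centerline$amplitude * sin(2 * pi * z / centerline$wavelength)
  } else {
    rep(0, length(z))
  }
}

ratio_at <- function(ratio, z, length) {
  if (length(ratio) == 1L) {
    rep(ratio, base::length(z))
  } else {
    ratio[1] + (ratio[2] - ratio[1]) * z / length
  }
}

# elliptical boundary radius from the centre: semi-axes chosen so that
# a/b = ratio (d_c/d_s) while preserving the geometric-mean radius r0
ellipse_radius <- function(theta, r0, ratio) {
  a <- r0 * sqrt(ratio)
  b <- r0 / sqrt(ratio)
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

#' Synthesize a fractional-Brownian surface field
#'
#' Spectral synthesis of a 2D fractional-Brownian field with power spectral
#' density proportional to `f^-(2H+2)`, periodic in the first (angular)
#' dimension. The second (axial) dimension is mirrored before the FFT so the
#' crop is free of wrap-around artefacts. The field is centred and scaled to
#' the requested RMS amplitude; deterministic for a fixed seed.
#'
#' @param n_theta,n_z Grid size (both >= 16).
#' @param H Hurst exponent, strictly in (0,1). The associated surface has
#'   theoretical fractal dimension `3 - H`.
#' @param amplitude_rms Target RMS of the field (mm); 0 returns zeros.
#' @param seed Integer seed; all randomness is local to this call.
#' @param oversample Spectral oversampling factor (default 4): the field is
#'   synthesized on a grid this many times finer and decimated, so that
#'   energy above the output Nyquist frequency folds back in and pixel-scale
#'   increments keep the `f^-(2H+2)` law. Without it, spectral truncation
#'   makes the smallest scales too smooth and scaling-exponent estimates
#'   biased.
#' @return An `n_theta` x `n_z` numeric matrix (mm).
#' @export
make_fbm_field <- function(n_theta, n_z, H, amplitude_rms, seed,
                           oversample = 4L) {
  if (n_theta < 16 || n_z < 16) {
    abort("`n_theta` and `n_z` must be >= 16.", class = "tracheasr_argument_error")
  }
  if (H <= 0 || H >= 1) {
    abort("`H` must be strictly in (0,1).", class = "tracheasr_argument_error")
  }
  if (amplitude_rms < 0) {
    abort("`amplitude_rms` must be >= 0.", class = "tracheasr_argument_error")
  }
  if (amplitude_rms == 0) {
    return(matrix(0, n_theta, n_z))
  }
  os <- max(1L, as.integer(oversample))
  nth <- os * n_theta
  nzz <- 2L * os * n_z # mirrored in z before the FFT
  fx <- c(seq(0, floor(nth / 2)), seq(-(ceiling(nth / 2) - 1), -1)) / nth
  fy <- c(seq(0, floor(nzz / 2)), seq(-(ceiling(nzz / 2) - 1), -1)) / nzz
  f <- sqrt(outer(fx^2, fy^2, `+`))
  amp <- ifelse(f > 0, f^(-(H + 1)), 0)
  field <- withr::with_seed(seed, {
    wn <- matrix(rnorm(nth * nzz), nth, nzz)
    spec <- fft(wn) * amp
    Re(fft(spec, inverse = TRUE)) / (nth * nzz)
  })
  field <- field[seq(1L, nth, by = os), seq(1L, os * n_z, by = os), drop = FALSE]
  field <- field - mean(field)
  field * amplitude_rms / sqrt(mean(field^2))
}

# look up perturbation p(theta, z) for arbitrary angles at slice k of the
# pre-generated field (linear interpolation in theta, periodic)
perturb_lookup <- function(field, theta, k) {
  n <- nrow(field)
  pos <- (theta %% (2 * pi)) / (2 * pi) * n # in [0, n)
  i0 <- floor(pos)
  fr <- pos - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  field[i0, k] * (1 - fr) + field[i1, k] * fr
}

#' Voxelize a tube phantom
#'
#' Renders a [tube_spec()] into a binary [voxel_mask()] together with a
#' ground-truth record (carina slice, per-slice diameter ratio, the
#' continuous perturbation field) for pipeline validation.
#'
#' @param spec A [tube_spec()].
#' @param spacing Voxel spacing in mm, default `c(0.6, 0.6, 1)`.
#' @return A list with elements `mask` (a [voxel_mask()]) and `truth`, a list
#'   holding `carina_slice` (index of the last single-lumen slice, `NA` if no
#'   bifurcation), `per_slice` (tibble of z index, z mm, d_c/d_s ratio),
#'   `center` (x,y of the mean axis in mm), `field` (the perturbation field
#'   matrix or NULL) and `spec`.
#' @export
make_tube_mask <- function(spec, spacing = c(0.6, 0.6, 1)) {
  stopifnot(inherits(spec, "tube_spec"))
  sx <- spacing[1]
  sy <- spacing[2]
  sz <- spacing[3]
  if (2 * spec$base_radius / max(sx, sy) < 8) {
    abort("Tube radius under-resolved: need >= 8 voxels across the diameter.",
      class = "tracheasr_resolution_error"
    )
  }
  nz <- max(1L, round(spec$length / sz))
  z_mm <- (seq_len(nz) - 0.5) * sz

  rmax_ell <- spec$base_radius * max(
    sqrt(max(spec$cross_section_ratio)),
    1 / sqrt(min(spec$cross_section_ratio))
  )
  bow <- if (identical(spec$centerline$kind, "bowed")) spec$centerline$amplitude else 0
  pert_marg <- switch(spec$perturbation$kind %||% "none",
    none = 0,
    fbm = 5 * spec$perturbation$amplitude_rms,
    sinusoid = spec$perturbation$amplitude
  )
  bif <- spec$bifurcation
  bif_marg <- 0
  if (!is.null(bif)) {
    ang <- bif$branch_angle * pi / 180
    r_child <- bif$child_radius_frac * spec$base_radius
    bif_marg <- r_child + tan(ang) * bif$z_split + r_child
  }
  half_x <- max(rmax_ell + bow + pert_marg, bif_marg) + 3 * sx
  half_y <- rmax_ell + pert_marg + 3 * sy
  nx <- 2L * ceiling(half_x / sx)
  ny <- 2L * ceiling(half_y / sy)
  cx0 <- nx * sx / 2
  cy0 <- ny * sy / 2

  field <- NULL
  if (identical(spec$perturbation$kind, "fbm") &&
    spec$perturbation$amplitude_rms > 0) {
    field <- make_fbm_field(
      256L, max(nz, 16L), spec$perturbation$H,
      spec$perturbation$amplitude_rms, spec$perturbation$seed
    )
    # Wall texture must be orthogonal to the tube's own parametric modes:
    # the theta-mean of p is a caliber change (belongs to r0(z)) and the
    # first theta-harmonic is a centerline shift (belongs to the
    # centerline), so both are projected out per slice; otherwise the
    # declared radius/centerline ground truth would be ambiguous.
    thg <- seq(0, 2 * pi, length.out = nrow(field) + 1L)[-(nrow(field) + 1L)]
    B <- cbind(1, cos(thg), sin(thg))
    field <- field - B %*% qr.solve(crossprod(B), crossprod(B, field))
    field <- field * spec$perturbation$amplitude_rms /
      sqrt(mean(field^2))
  }

  xs <- (seq_len(nx) - 0.5) * sx
  ys <- (seq_len(ny) - 0.5) * sy
  ratio_z <- ratio_at(spec$cross_section_ratio, z_mm, spec$length)
  bow_z <- centerline_offset(spec$centerline, z_mm)

  arr <- array(0L, dim = c(nx, ny, nz))
  dx0 <- matrix(xs, nx, ny) - cx0
  dy0 <- matrix(ys, nx, ny, byrow = TRUE) - cy0
  for (k in seq_len(nz)) {
    dx <- dx0 - bow_z[k]
    dy <- dy0
    in_parent <- is.null(bif) || z_mm[k] >= bif$z_split
    if (in_parent) {
      th <- atan2(dy, dx)
      rr <- sqrt(dx^2 + dy^2)
      bound <- ellipse_radius(th, spec$base_radius, ratio_z[k])
      if (!is.null(field)) {
        bound <- bound + perturb_lookup(field, th, k)
      } else if (identical(spec$perturbation$kind, "sinusoid")) {
        p <- spec$perturbation
        bound <- bound + p$amplitude * cos(p$n_theta_cycles * th) *
          cos(2 * pi * p$n_z_cycles * z_mm[k] / spec$length)
      }
      arr[, , k] <- (rr <= bound) * 1L
    } else {
      off <- r_child + tan(ang) * (bif$z_split - z_mm[k])
      d1 <- sqrt((dx - off)^2 + dy^2)
      d2 <- sqrt((dx + off)^2 + dy^2)
      arr[, , k] <- (pmin(d1, d2) <= r_child) * 1L
    }
  }

  carina <- NA_integer_
  if (!is.null(bif)) {
    single <- z_mm >= bif$z_split
    if (!any(single)) {
      abort("Bifurcation z_split leaves no single-lumen slice.",
        class = "tracheasr_argument_error"
      )
    }
    carina <- min(which(single))
  }
  list(
    mask = voxel_mask(arr, spacing),
    truth = list(
      carina_slice = carina,
      per_slice = tibble(z = seq_len(nz), z_mm = z_mm, ratio = ratio_z),
      center = c(x = cx0, y = cy0),
      bow = bow_z,
      field = field,
      spec = spec,
      spacing = spacing
    )
  )
}

#' Generate small height maps with known box-counting behaviour
#'
#' Oracle inputs for the fractal estimator: flat, ramp and checkerboard maps
#' have closed-form differential box counts; quantized fractional-Brownian
#' maps have known theoretical dimension `3 - H`.
#'
#' @param kind One of `"constant"`, `"ramp"`, `"checkerboard"`, `"fbm"`.
#' @param dims Map size in pixels, length 2 (default `c(64, 64)`).
#' @param value Gray level of the constant map.
#' @param n_levels Gray levels spanned by the ramp / checkerboard.
#' @param H,amplitude_rms_levels,seed Parameters of the fbm map: Hurst
#'   exponent, RMS amplitude expressed in gray levels, and seed.
#' @return A [heightmap()].
#' @export
make_test_heightmap <- function(kind, dims = c(64, 64), value = 0,
                                n_levels = 8, H = 0.5,
                                amplitude_rms_levels = 40, seed = 1) {
  px <- switch(kind,
    constant = matrix(as.integer(value), dims[1], dims[2]),
    ramp = {
      col_vals <- round_half_up(
        (seq_len(dims[2]) - 1) / max(1, dims[2] - 1) * (n_levels - 1)
      )
      matrix(as.integer(col_vals), dims[1], dims[2], byrow = TRUE)
    },
    checkerboard = {
      par_ <- outer(seq_len(dims[1]), seq_len(dims[2]), `+`) %% 2L
      matrix(as.integer(par_ * (n_levels - 1)), dims[1], dims[2])
    },
    fbm = {
      f <- make_fbm_field(dims[1], dims[2], H, amplitude_rms_levels, seed)
      matrix(as.integer(round_half_up(f - min(f))), dims[1], dims[2])
    },
    abort(sprintf("Unknown height-map kind '%s'.", kind),
      class = "tracheasr_argument_error"
    )
  )
  heightmap(px)
}

#' Serialize a tube spec to a plain-text (YAML) file
#'
#' @param spec A [tube_spec()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_tube_spec <- function(spec, path) {
  stopifnot(inherits(spec, "tube_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a tube spec from a YAML file written by [write_tube_spec()]
#'
#' @param path Source file.
#' @return A [tube_spec()].
#' @export
read_tube_spec <- function(path) {
  x <- yaml::read_yaml(path)
  tube_spec(
    base_radius = x$base_radius, length = x$length,
    centerline = x$centerline,
    cross_section_ratio = unlist(x$cross_section_ratio),
    perturbation = x$perturbation,
    bifurcation = x$bifurcation
  )
}
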