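# Per-case measurement record: SR_S / SR_C / SR_T, tracheal index, LAA-950,
# and the batch driver.

#' Analysis configuration
#'
#' Every tunable of the pipeline in one place, with a content hash embedded
#' in outputs so results are traceable to the exact settings.
#'
#' @param top_offset_mm Offset below the top slice where analysis starts.
#' @param min_length_mm Minimum analyzable segment length.
#' @param n_theta Angular samples of the unrolled surface.
#' @param dz_mm Axial resampling interval.
#' @param smoothing_span_mm Mean-radius trend smoothing span.
#' @param min_branch_area_mm2,branch_persistence Carina-detection thresholds.
#' @param ti_window_mm Inferior margin of the tracheal-index window above the
#'   carina (default 20 mm).
#' @param z_carina Optional manual carina slice index (overrides detection).
#' @return A list of class `sr_config` with a `hash` element.
#' @export
sr_config <- function(top_offset_mm = 5, min_length_mm = 20,
                      n_theta = 360L, dz_mm = 1, smoothing_span_mm = 15,
                      min_branch_area_mm2 = 20, branch_persistence = 3L,
                      ti_window_mm = 20, z_carina = NULL) {
  cfg <- list(
    top_offset_mm = top_offset_mm, min_length_mm = min_length_mm,
    n_theta = as.integer(n_theta), dz_mm = dz_mm,
    smoothing_span_mm = smoothing_span_mm,
    min_branch_area_mm2 = min_branch_area_mm2,
    branch_persistence = as.integer(branch_persistence),
    ti_window_mm = ti_window_mm, z_carina = z_carina
  )
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "sr_config")
}

# per-slice coronal (x) and sagittal (y) lumen extents
slice_extents_voxel <- function(segment) {
  mask <- segment$mask
  sx <- mask$spacing[1]
  sy <- mask$spacing[2]
  sz <- mask$spacing[3]
  ks <- seq(segment$z_carina, segment$z_top)
  purrr::map_dfr(ks, function(k) {
    sl <- mask$data[, , k]
    fg <- which(sl > 0)
    nr <- nrow(sl)
    ri <- (fg - 1L) %% nr + 1L
    ci <- (fg - 1L) %/% nr + 1L
    tibble(
      z = k, z_mm = (k - 0.5) * sz,
      d_c = (diff(range(ri)) + 1L) * sx,
      d_s = (diff(range(ci)) + 1L) * sy
    )
  })
}

# sub-voxel extents from the unrolled surface (boundary about the per-slice
# centroid: r_total minus the drift projection)
slice_extents_surface <- function(surface) {
  theta <- surface$theta_grid
  drift <- sweep(surface$centroids, 2, colMeans(surface$centroids))
  proj <- outer(cos(theta), drift[, 1]) + outer(sin(theta), drift[, 2])
  r_meas <- surface$r_total - proj
  x <- sweep(r_meas * cos(theta), 2, surface$centroids[, 1], `+`)
  y <- sweep(r_meas * sin(theta), 2, surface$centroids[, 2], `+`)
  tibble(
    z_mm = surface$z_grid,
    d_c = apply(x, 2, function(v) diff(range(v))),
    d_s = apply(y, 2, function(v) diff(range(v)))
  )
}

#' Tracheal index
#'
#' Minimum ratio of coronal (left-right) to sagittal (anterior-posterior)
#' lumen diameter over the analysis window, which by default runs from 2 cm
#' above the carina up to the top of the analyzed segment. Diameters are
#' measured on the sub-voxel unrolled boundary when `surface` is supplied,
#' else as voxel extents.
#'
#' @param segment A [crop_trachea()] result.
#' @param surface Optional [radial_sample()] result for sub-voxel extents.
#' @param window Optional integer slice range `c(lo, hi)` overriding the
#'   default `[z_carina + round(20/sz), z_top]`.
#' @param ti_window_mm Inferior margin above the carina for the default
#'   window (default 20 mm).
#' @return List with `TI`, `TI_slice` (slice index attaining the minimum),
#'   and `per_slice`, a tibble of `z`, `z_mm`, `d_c`, `d_s`, `ratio`,
#'   `in_window`.
#' @export
tracheal_index <- function(segment, surface = NULL, window = NULL,
                           ti_window_mm = 20) {
  stopifnot(inherits(segment, "trachea_segment"))
  sz <- segment$mask$spacing[3]
  if (is.null(window)) {
    window <- c(segment$z_carina + round_half_up(ti_window_mm / sz), segment$z_top)
  }
  if (window[1] > window[2]) {
    abort("Empty tracheal-index window.", class = "tracheasr_window_error")
  }
  if (is.null(surface)) {
    tab <- slice_extents_voxel(segment)
    tab$z_slice <- tab$z
  } else {
    tab <- slice_extents_surface(surface)
    tab$z_slice <- round_half_up(tab$z_mm / sz + 0.5)
    tab$z <- tab$z_slice
  }
  tab$ratio <- tab$d_c / tab$d_s
  tab$in_window <- tab$z_slice >= window[1] & tab$z_slice <= window[2]
  win <- tab[tab$in_window, ]
  if (!nrow(win)) {
    abort("Tracheal-index window contains no slices.",
      class = "tracheasr_window_error"
    )
  }
  i <- which.min(win$ratio)
  list(
    TI = win$ratio[i],
    TI_slice = win$z[i],
    per_slice = tab[, c("z", "z_mm", "d_c", "d_s", "ratio", "in_window")]
  )
}

#' Percentage of lung voxels below -950 HU
#'
#' The standard CT emphysema measure: the percentage of voxels inside the
#' lung mask with attenuation strictly below -950 Hounsfield units (a voxel
#' at exactly -950 HU is not counted).
#'
#' @param ct A [ct_volume()].
#' @param lung_mask A [voxel_mask()] on the same grid.
#' @return LAA-950 percentage.
#' @export
laa950 <- function(ct, lung_mask) {
  stopifnot(inherits(ct, "ct_volume"), inherits(lung_mask, "voxel_mask"))
  if (!identical(dim(ct$data), dim(lung_mask$data)) ||
    !isTRUE(all.equal(ct$spacing, lung_mask$spacing))) {
    abort("CT volume and lung mask must share shape and spacing exactly.",
      class = "tracheasr_pairing_error"
    )
  }
  inside <- lung_mask$data > 0
  n <- sum(inside)
  if (n == 0L) {
    abort("Lung mask is empty.", class = "tracheasr_degenerate_input_error")
  }
  100 * sum(ct$data[inside] < -950) / n
}

#' Run the full trachea surface-roughness pipeline on one mask
#'
#' Carina detection, trachea cropping, cylindrical unrolling, shape /
#' curvature / total decomposition, fractal estimation of each component and
#' the tracheal index, with every warning raised en route collected as a QC
#' flag.
#'
#' @param mask A [voxel_mask()].
#' @param config An [sr_config()].
#' @return An object of class `trachea_metrics`; see [glance.trachea_metrics()]
#'   for the one-row summary and [tidy.trachea_metrics()] for per-slice
#'   diameters. The fitted `fractal_result` objects, the decomposed surface
#'   and the segment are attached as list elements.
#' @export
compute_all <- function(mask, config = sr_config()) {
  stopifnot(inherits(mask, "voxel_mask"))
  qc <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      qc <<- c(qc, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  cc <- label_components_3d(mask$data)
  z_carina <- config$z_carina %||% collect(find_carina(
    mask,
    min_area_mm2 = config$min_branch_area_mm2,
    persistence = config$branch_persistence,
    cc = cc
  ))
  segment <- collect(crop_trachea(
    mask, z_carina,
    top_offset_mm = config$top_offset_mm,
    min_length_mm = config$min_length_mm,
    cc = cc
  ))
  surface <- collect(radial_sample(
    segment,
    n_theta = config$n_theta, dz_mm = config$dz_mm
  ))
  surface <- decompose(surface, smoothing_span_mm = config$smoothing_span_mm)
  fr <- purrr::map(
    rlang::set_names(c("shape", "curvature", "total")),
    function(comp) collect(fractal_estimate(to_heightmap(surface, comp)))
  )
  ti <- collect(tracheal_index(
    segment, surface,
    ti_window_mm = config$ti_window_mm
  ))
  metrics <- tibble(
    SR_S = fr$shape$SR, SR_C = fr$curvature$SR, SR_T = fr$total$SR,
    D_S = fr$shape$D, D_C = fr$curvature$D, D_T = fr$total$D,
    fit_r2_S = fr$shape$fit_r2, fit_r2_C = fr$curvature$fit_r2,
    fit_r2_T = fr$total$fit_r2,
    TI = ti$TI, TI_slice = ti$TI_slice,
    z_carina = segment$z_carina, z_top = segment$z_top,
    n_slices = segment$z_top - segment$z_carina + 1L,
    n_qc_flags = length(qc),
    config_hash = config$hash
  )
  structure(
    list(
      metrics = metrics,
      per_slice_diameters = ti$per_slice,
      fractal = fr,
      surface = surface,
      segment = segment,
      qc_flags = qc,
      config = config
    ),
    class = "trachea_metrics"
  )
}

#' @export
print.trachea_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<trachea_metrics> SR_S %.1f%%  SR_C %.1f%%  SR_T %.1f%%  TI %.3f (%d QC flags)\n",
    m$SR_S, m$SR_C, m$SR_T, m$TI, m$n_qc_flags
  ))
  invisible(x)
}

#' One-row summary of a trachea analysis
#'
#' @param x A `trachea_metrics` object.
#' @param ... Unused.
#' @return One-row tibble: SR and D for each component, fit R^2, TI and its
#'   slice, segment extent, QC flag count and configuration hash.
#' @method glance trachea_metrics
#' @export
glance.trachea_metrics <- function(x, ...) {
  x$metrics
}

#' Per-slice diameter table of a trachea analysis
#'
#' @param x A `trachea_metrics` object.
#' @param ... Unused.
#' @return Tibble of per-slice coronal and sagittal diameters and their
#'   ratio, flagged by tracheal-index window membership.
#' @method tidy trachea_metrics
#' @export
tidy.trachea_metrics <- function(x, ...) {
  x$per_slice_diameters
}

#' Batch-process a directory of masks
#'
#' Runs [compute_all()] on every NIfTI mask found, recording per-case
#' failures without aborting the batch.
#'
#' @param input Directory containing `.nii`/`.nii.gz` masks, or a character
#'   vector of file paths.
#' @param output_csv Optional path; when given the result table is written
#'   as CSV.
#' @param config An [sr_config()].
#' @return A tibble with one row per case: the [glance.trachea_metrics()]
#'   columns plus `case_id`, `status` and `qc_flags` (collapsed).
#' @export
run_batch <- function(input, output_csv = NULL, config = sr_config()) {
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  } else {
    input
  }
  if (length(input) == 1L && !dir.exists(input) && !file.exists(input)) {
    abort(sprintf("Cannot read input '%s'.", input), class = "tracheasr_io_error")
  }
  empty <- tibble(
    SR_S = NA_real_, SR_C = NA_real_, SR_T = NA_real_,
    D_S = NA_real_, D_C = NA_real_, D_T = NA_real_,
    fit_r2_S = NA_real_, fit_r2_C = NA_real_, fit_r2_T = NA_real_,
    TI = NA_real_, TI_slice = NA_integer_,
    z_carina = NA_integer_, z_top = NA_integer_, n_slices = NA_integer_,
    n_qc_flags = NA_integer_, config_hash = config$hash
  )
  rows <- purrr::map(files, function(f) {
    res <- tryCatch(
      {
        tm <- compute_all(read_mask(f), config)
        dplyr::bind_cols(
          tibble(case_id = basename(f)),
          glance(tm),
          tibble(
            status = "ok",
            qc_flags = paste(tm$qc_flags, collapse = " | ")
          )
        )
      },
      error = function(e) {
        dplyr::bind_cols(
          tibble(case_id = basename(f)),
          empty,
          tibble(status = paste0("failed: ", conditionMessage(e)), qc_flags = "")
        )
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(output_csv)) {
    readr::write_csv(out, output_csv)
  }
  out
}
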