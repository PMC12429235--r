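# Cylindrical unrolling of the trachea lumen: sub-voxel boundary sampling
# on rays from the per-slice centroid, re-centred onto the segment-mean
# axis, then decomposed into shape, curvature and total components.
#
# r_total(theta, z) is the lumen radius about the segment-mean axis:
# radii are measured from the per-slice centroid (which keeps every ray
# star-shaped) and the centroid-drift projection drift_x cos(theta) +
# drift_y sin(theta) is added back, so global bending of the centerline is
# present in the total surface and can be attributed to the curvature
# component by decompose().

#' Sample the lumen surface onto an angle-by-axial radius grid
#'
#' For each analyzed slice the lumen centroid is computed and `n_theta` rays
#' are cast from it; the boundary reference point on each ray is the
#' sub-voxel position where the bilinear interpolation of the mask crosses
#' 0.5 (first crossing from inside out). Per-slice radii are re-centred onto
#' the segment-mean axis and resampled along z to a uniform `dz_mm` grid.
#' Isolated failed rays (< 2% of a slice) are filled by circular linear
#' interpolation over theta.
#'
#' @param segment A [crop_trachea()] result.
#' @param n_theta Number of equally spaced angles in `[0, 2*pi)`; theta = 0
#'   points along +x (patient left), counter-clockwise seen from superior.
#' @param dz_mm Axial resampling interval in mm (default 1).
#' @return An object of class `radial_surface`: `theta_grid`, `z_grid` (mm,
#'   absolute canonical positions), `r_total` (n_theta x n_z, mm),
#'   `centroids` (n_z x 2, mm), `mean_center` (x,y mm), plus `n_failed_rays`
#'   and `n_nonstar_slices` diagnostics. Shape/curvature components are
#'   filled in by [decompose()].
#' @export
radial_sample <- function(segment, n_theta = 360L, dz_mm = 1) {
  stopifnot(inherits(segment, "trachea_segment"))
  mask <- segment$mask
  sx <- mask$spacing[1]
  sy <- mask$spacing[2]
  sz <- mask$spacing[3]
  ks <- seq(segment$z_carina, segment$z_top)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ct <- cos(theta)
  st <- sin(theta)
  dr <- 0.25 * min(sx, sy)

  r_slices <- matrix(NA_real_, n_theta, length(ks))
  cent <- matrix(NA_real_, length(ks), 2)
  n_failed <- 0L
  n_nonstar <- 0L
  for (jj in seq_along(ks)) {
    k <- ks[jj]
    sl <- mask$data[, , k]
    fg <- which(sl > 0)
    if (!length(fg)) {
      abort(sprintf("Slice %d of the segment has no lumen.", k),
        class = "tracheasr_degenerate_slice_error"
      )
    }
    nr <- nrow(sl)
    ri <- (fg - 1L) %% nr + 1L
    ci <- (fg - 1L) %/% nr + 1L
    cx <- mean((ri - 0.5) * sx)
    cy <- mean((ci - 0.5) * sy)
    cent[jj, ] <- c(cx, cy)

    # bounding radius: farthest foreground voxel + 2 voxels
    rmax <- sqrt(max(((ri - 0.5) * sx - cx)^2 + ((ci - 0.5) * sy - cy)^2)) +
      2 * max(sx, sy)
    rr <- seq(0, rmax, by = dr)
    nrr <- length(rr)
    xi <- (outer(ct, rr) + cx) / sx + 0.5
    yi <- (outer(st, rr) + cy) / sy + 0.5
    v <- matrix(bilinear_at(sl, as.vector(xi), as.vector(yi)), n_theta, nrr)

    outside <- v < 0.5
    j_first <- max.col(outside, ties.method = "first")
    has_cross <- rowSums(outside) > 0 & !outside[, 1]
    rad <- rep(NA_real_, n_theta)
    ok <- which(has_cross)
    if (length(ok)) {
      j <- j_first[ok]
      v1 <- v[cbind(ok, j - 1L)]
      v0 <- v[cbind(ok, j)]
      rad[ok] <- rr[j - 1L] + dr * (v1 - 0.5) / (v1 - v0)
    }
    # non-star-shaped: mask re-entered beyond the first crossing
    if (length(ok)) {
      inside <- !outside
      last_in <- nrr + 1L - max.col(inside[, nrr:1, drop = FALSE],
        ties.method = "first"
      )
      if (any(last_in[ok] > j_first[ok])) {
        n_nonstar <- n_nonstar + 1L
        warn(sprintf(
          "Slice %d: non-star-shaped lumen on %d ray(s); first crossing used.",
          k, sum(last_in[ok] > j_first[ok])
        ), class = "tracheasr_nonstar_warning")
      }
    }
    bad <- which(is.na(rad))
    if (length(bad) > 0.02 * n_theta) {
      abort(sprintf(
        "Slice %d: %d of %d rays failed to find a boundary.",
        k, length(bad), n_theta
      ), class = "tracheasr_degenerate_slice_error")
    }
    if (length(bad)) {
      n_failed <- n_failed + length(bad)
      good <- which(!is.na(rad))
      # circular interpolation: extend by one period on each side
      xg <- c(good - n_theta, good, good + n_theta)
      yg <- rep(rad[good], 3)
      rad[bad] <- approx(xg, yg, xout = bad)$y
    }
    r_slices[, jj] <- rad
  }

  mean_center <- colMeans(cent)
  drift <- sweep(cent, 2, mean_center)
  # re-centre radii onto the segment-mean axis (first order)
  r_axis <- r_slices + outer(ct, drift[, 1]) + outer(st, drift[, 2])

  # resample along z to uniform dz
  z_in <- (ks - 0.5) * sz
  z_out <- seq(z_in[1], z_in[length(z_in)], by = dz_mm)
  if (length(z_in) > 1L && !isTRUE(all.equal(sz, dz_mm))) {
    r_total <- t(apply(r_axis, 1, function(col) approx(z_in, col, xout = z_out)$y))
    cent_out <- cbind(
      approx(z_in, cent[, 1], xout = z_out)$y,
      approx(z_in, cent[, 2], xout = z_out)$y
    )
  } else {
    z_out <- z_in
    r_total <- r_axis
    cent_out <- cent
  }
  structure(
    list(
      theta_grid = theta,
      z_grid = z_out,
      r_total = r_total,
      centroids = cent_out,
      mean_center = mean_center,
      r_shape = NULL,
      r_curvature = NULL,
      mean_radius = NULL,
      n_failed_rays = n_failed,
      n_nonstar_slices = n_nonstar,
      dz_mm = if (length(z_out) > 1L) z_out[2] - z_out[1] else dz_mm
    ),
    class = "radial_surface"
  )
}

#' Decompose the total surface into shape and curvature components
#'
#' The curvature component captures global geometry: the projection of the
#' per-slice centroid drift (centroid minus segment-mean centroid) onto each
#' ray direction, plus the axially smoothed mean-radius trend minus the
#' overall mean radius. The shape component is the residual texture:
#' `r_shape = r_total - mean_radius(z) - r_curvature`, so the decomposition
#' is additive by construction.
#'
#' @param surface A [radial_sample()] result.
#' @param smoothing_span_mm Moving-average span (mm) for the mean-radius
#'   trend (default 15).
#' @return The surface with `r_shape`, `r_curvature` and `mean_radius`
#'   populated.
#' @export
decompose <- function(surface, smoothing_span_mm = 15) {
  stopifnot(inherits(surface, "radial_surface"))
  theta <- surface$theta_grid
  r_total <- surface$r_total
  n_z <- ncol(r_total)
  mean_r <- colMeans(r_total)
  drift <- sweep(surface$centroids, 2, colMeans(surface$centroids))
  proj <- outer(cos(theta), drift[, 1]) + outer(sin(theta), drift[, 2])
  width <- max(1L, round_half_up(smoothing_span_mm / surface$dz_mm))
  trend <- moving_average(mean_r, width) - mean(mean_r)
  r_curv <- proj + matrix(trend, nrow(r_total), n_z, byrow = TRUE)
  r_shape <- r_total - matrix(mean_r, nrow(r_total), n_z, byrow = TRUE) - r_curv
  surface$mean_radius <- mean_r
  surface$r_curvature <- r_curv
  surface$r_shape <- r_shape
  surface$smoothing_span_mm <- smoothing_span_mm
  surface
}

surface_component <- function(surface, component = c("total", "shape", "curvature")) {
  component <- match.arg(component)
  m <- switch(component,
    total = surface$r_total,
    shape = surface$r_shape,
    curvature = surface$r_curvature
  )
  if (is.null(m)) {
    abort(sprintf(
      "Component '%s' not populated; run decompose() first.", component
    ), class = "tracheasr_state_error")
  }
  m
}

#' Tidy a radial surface into a long tibble
#'
#' @param x A `radial_surface`.
#' @param ... Unused.
#' @return A tibble with columns `theta`, `z_mm`, `r_total` and, when
#'   populated, `r_shape`, `r_curvature`.
#' @method tidy radial_surface
#' @export
tidy.radial_surface <- function(x, ...) {
  out <- tibble(
    theta = rep(x$theta_grid, times = length(x$z_grid)),
    z_mm = rep(x$z_grid, each = length(x$theta_grid)),
    r_total = as.vector(x$r_total)
  )
  if (!is.null(x$r_shape)) {
    out$r_shape <- as.vector(x$r_shape)
    out$r_curvature <- as.vector(x$r_curvature)
  }
  out
}

#' @export
print.radial_surface <- function(x, ...) {
  cat(sprintf(
    "<radial_surface> %d angles x %d axial positions (dz = %.3g mm)%s\n",
    length(x$theta_grid), length(x$z_grid), x$dz_mm,
    if (is.null(x$r_shape)) "" else ", decomposed"
  ))
  invisible(x)
}

#' Render an unrolled surface to a grayscale PNG
#'
#' Writes a 16-bit grayscale image of the unrolled surface (theta horizontal,
#' z vertical, brighter = topological hills) plus a plain-text sidecar
#' recording the mm-per-gray scale. Purely diagnostic.
#'
#' @param surface A [radial_surface()].
#' @param component `"shape"`, `"curvature"` or `"total"`.
#' @param path Output PNG path; the sidecar is written to `paste0(path, ".txt")`.
#' @return `path`, invisibly.
#' @export
render_unrolled <- function(surface, component = "total", path) {
  m <- surface_component(surface, component)
  rng <- range(m)
  span <- diff(rng)
  img <- if (span > 0) (m - rng[1]) / span else matrix(0.5, nrow(m), ncol(m))
  # theta horizontal, z vertical with superior at the top row
  img <- t(img)[rev(seq_len(ncol(m))), , drop = FALSE]
  png::writePNG(img, target = path)
  writeLines(
    c(
      sprintf("component: %s", component),
      sprintf("gray_levels: 65535"),
      sprintf("mm_per_gray: %.10g", if (span > 0) span / 65535 else 0),
      sprintf("min_mm: %.6f", rng[1]),
      sprintf("max_mm: %.6f", rng[2])
    ),
    paste0(path, ".txt")
  )
  invisible(path)
}

#' Plot a radial surface
#'
#' Unrolled raster view of one component (theta horizontal, z vertical).
#'
#' @param object A `radial_surface`.
#' @param component `"total"`, `"shape"` or `"curvature"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_surface
#' @export
autoplot.radial_surface <- function(object, component = "total", ...) {
  m <- surface_component(object, component)
  df <- tibble(
    theta = rep(object$theta_grid, times = ncol(m)),
    z_mm = rep(object$z_grid, each = nrow(m)),
    height = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$z_mm, fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(
      x = expression(theta ~ "(rad)"), y = "z (mm)",
      fill = "height (mm)",
      title = sprintf("Unrolled trachea surface (%s)", component)
    ) +
    ggplot2::theme_minimal()
}

#' Silhouette-style rolled view of the lumen surface
#'
#' Projects the reconstructed boundary onto the coronal plane as a shaded
#' silhouette, a quick rolled-surface diagnostic companion to
#' [autoplot.radial_surface()].
#'
#' @param surface A `radial_surface`.
#' @return A ggplot.
#' @export
plot_rolled <- function(surface) {
  theta <- surface$theta_grid
  n_z <- length(surface$z_grid)
  x <- surface$mean_center[1] + surface$r_total * cos(theta)
  df <- tibble(
    z_mm = rep(surface$z_grid, each = length(theta)),
    x_mm = as.vector(x),
    depth = rep(sin(theta), times = n_z)
  )
  ggplot2::ggplot(
    df[df$depth >= 0, ],
    ggplot2::aes(x = .data$x_mm, y = .data$z_mm, colour = .data$depth)
  ) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_gradient(low = "grey20", high = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", colour = "depth") +
    ggplot2::theme_minimal()
}
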