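# Trachea isolation: carina detection by persistent in-slice component
# split, then cropping between ~5 mm below the top slice and the carina,
# retaining only the component continuous with the tracheal lumen.

#' Detect the carina slice in an airway-tree mask
#'
#' Tracks the largest 26-connected airway component from the most superior
#' slice downward and returns the index of the last single-lumen slice: the
#' slice immediately above the first split into two or more in-slice
#' 8-connected components, each of at least `min_area_mm2`, that persists
#' for at least `persistence` consecutive slices.
#'
#' @param mask A [voxel_mask()] that [validate_airway_mask()] reports usable.
#' @param min_area_mm2 Minimum in-slice area (mm^2) for a cross-section to
#'   count as a branch (default 20).
#' @param persistence Number of consecutive split slices required (default 3).
#' @param cc Optional precomputed component labeling (internal reuse).
#' @return Integer slice index of the carina (canonical space).
#' @export
find_carina <- function(mask, min_area_mm2 = 20, persistence = 3L,
                        cc = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  cc <- cc %||% label_components_3d(mask$data)
  val <- validate_airway_mask(mask, cc = cc)
  if (!val$usable) {
    abort(paste0(
      "Mask unusable for carina detection: ",
      paste(val$reasons, collapse = "; ")
    ), class = "tracheasr_carina_error")
  }
  largest <- which.max(cc$sizes)
  nz <- dim(mask$data)[3]
  vox_area <- mask$spacing[1] * mask$spacing[2]
  min_px <- min_area_mm2 / vox_area

  # per slice: number of qualifying cross-sections belonging to the main tree
  n_branch <- integer(nz)
  for (k in seq_len(nz)) {
    gl <- cc$global[[k]]
    if (!length(gl)) next
    labs <- which(gl == largest)
    if (!length(labs)) next
    sl <- cc$slice_labels[[k]]
    cnt <- tabulate(sl, nbins = max(sl))
    n_branch[k] <- sum(cnt[labs] >= min_px)
  }
  present <- which(n_branch >= 1L)
  if (!length(present)) {
    abort("Main component has no qualifying cross-sections.",
      class = "tracheasr_carina_error"
    )
  }
  top <- max(present)
  for (k in seq(top, min(present), by = -1L)) {
    lo <- k - persistence + 1L
    if (lo < 1L) break
    if (all(n_branch[lo:k] >= 2L)) {
      if (k == top) {
        abort("Airway splits at the very top slice; no trachea above the carina.",
          class = "tracheasr_carina_error"
        )
      }
      # most superior persistent split: continue scanning upward? We scan
      # top-down, so the first k satisfying the window IS the most superior.
      return(k + 1L)
    }
  }
  abort(paste0(
    "No persistent bifurcation found; the mask may contain only the ",
    "trachea. Supply `z_carina` manually to crop_trachea()."
  ), class = "tracheasr_carina_error")
}

#' Crop the trachea analysis segment
#'
#' Locates the most superior slice containing the tracheal component, starts
#' the analysis `top_offset_mm` below it (rounded to whole slices), ends at
#' the carina, and within each analyzed slice keeps only the connected
#' component continuous with the tracheal lumen (largest-overlap tracking
#' from the top slice down).
#'
#' @param mask A [voxel_mask()].
#' @param z_carina Carina slice index, e.g. from [find_carina()].
#' @param top_offset_mm Offset below the top slice where analysis starts
#'   (default 5 mm).
#' @param min_length_mm Minimum analyzable segment length (default 20 mm).
#' @param cc Optional precomputed component labeling (internal reuse).
#' @return An object of class `trachea_segment`: list with `mask` (cropped
#'   [voxel_mask()], same grid, zero outside the segment), `z_top`,
#'   `z_carina`, `slice_range`, and `provenance`.
#' @export
crop_trachea <- function(mask, z_carina, top_offset_mm = 5,
                         min_length_mm = 20, cc = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  nz <- dim(mask$data)[3]
  sz <- mask$spacing[3]
  if (z_carina < 1L || z_carina > nz) {
    abort("`z_carina` outside the mask.", class = "tracheasr_argument_error")
  }
  cc <- cc %||% label_components_3d(mask$data)
  if (!length(cc$sizes)) {
    abort("Mask has no foreground.", class = "tracheasr_argument_error")
  }
  largest <- which.max(cc$sizes)
  present <- which(vapply(
    seq_len(nz), function(k) largest %in% cc$global[[k]], logical(1)
  ))
  present <- present[present >= z_carina]
  if (!length(present)) {
    abort("No tracheal foreground above the carina.",
      class = "tracheasr_argument_error"
    )
  }
  z_top_full <- max(present)
  z_top <- z_top_full - round_half_up(top_offset_mm / sz)
  if ((z_top - z_carina + 1) * sz < min_length_mm) {
    abort(sprintf(
      "Analysis segment too short: %.0f mm < %.0f mm minimum.",
      (z_top - z_carina + 1) * sz, min_length_mm
    ), class = "tracheasr_segment_error")
  }

  out <- array(0L, dim = dim(mask$data))
  prev_kept <- NULL
  for (k in seq(z_top, z_carina, by = -1L)) {
    sl <- cc$slice_labels[[k]]
    gl <- cc$global[[k]]
    cand <- which(gl == largest)
    if (!length(cand)) {
      abort(sprintf("Tracheal component absent from slice %d.", k),
        class = "tracheasr_segment_error"
      )
    }
    cnt <- tabulate(sl, nbins = max(sl))
    if (is.null(prev_kept)) {
      keep <- cand[which.max(cnt[cand])]
    } else {
      pd <- dilate3x3(prev_kept)
      ov <- vapply(cand, function(l) sum(pd & sl == l), numeric(1))
      keep <- if (any(ov > 0)) cand[which.max(ov)] else cand[which.max(cnt[cand])]
    }
    kept <- sl == keep
    out[, , k] <- kept * 1L
    prev_kept <- kept
  }
  structure(
    list(
      mask = voxel_mask(out, mask$spacing, mask$origin),
      z_top = as.integer(z_top),
      z_carina = as.integer(z_carina),
      slice_range = c(as.integer(z_carina), as.integer(z_top)),
      provenance = list(
        z_top_full = as.integer(z_top_full),
        top_offset_mm = top_offset_mm,
        top_offset_slices = round_half_up(top_offset_mm / sz)
      )
    ),
    class = "trachea_segment"
  )
}

#' @export
print.trachea_segment <- function(x, ...) {
  cat(sprintf(
    "<trachea_segment> slices [%d, %d] (%d slices, %.0f mm)\n",
    x$z_carina, x$z_top, x$z_top - x$z_carina + 1L,
    (x$z_top - x$z_carina + 1L) * x$mask$spacing[3]
  ))
  invisible(x)
}
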