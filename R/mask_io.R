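# NIfTI mask input/output and validation.
#
# Canonical orientation: x increases toward the patient's left (the coronal
# diameter axis), y toward anterior (the sagittal diameter axis), z toward
# superior ("LAS" in xform terms). All slice indices downstream are in this
# space. Loaders reorient using the NIfTI qform/sform when present and record
# the transformation applied; images without a spatial transform are assumed
# already canonical.

#' Construct a voxel mask
#'
#' A `voxel_mask` is a 3D binary array with voxel spacing in millimetres and
#' a physical origin, in canonical orientation (x = left-right, y =
#' anterior-posterior, z = inferior to superior).
#'
#' @param data 3D array; any nonzero voxel is foreground.
#' @param spacing Numeric length-3, voxel spacing in mm; all strictly
#'   positive and finite.
#' @param origin Numeric length-3, physical position of voxel (1,1,1) in mm.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "tracheasr_dim_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive finite values (mm).",
      class = "tracheasr_metadata_error"
    )
  }
  storage.mode(data) <- "integer"
  data[data != 0L] <- 1L
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "voxel_mask"
  )
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_mask> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d foreground\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$data)
  ))
  invisible(x)
}

#' Construct a CT volume
#'
#' Attenuation values in Hounsfield units on the same canonical grid
#' convention as [voxel_mask()].
#'
#' @param data 3D numeric array of HU values.
#' @inheritParams voxel_mask
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "tracheasr_dim_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive finite values (mm).",
      class = "tracheasr_metadata_error"
    )
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

read_nifti_canonical <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': file does not exist.", path),
      class = "tracheasr_io_error"
    )
  }
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    abort(
      sprintf("'%s': MetaImage is not supported; convert to NIfTI-1 (.nii/.nii.gz).", path),
      class = "tracheasr_io_error"
    )
  }
  img <- tryCatch(RNifti::readNifti(path),
    error = function(e) {
      abort(sprintf("Cannot read '%s' as NIfTI: %s", path, conditionMessage(e)),
        class = "tracheasr_io_error"
      )
    }
  )
  hdr <- RNifti::niftiHeader(img)
  flips <- "none"
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    ori <- RNifti::orientation(img)
    if (!identical(ori, "LAS")) {
      RNifti::orientation(img) <- "LAS"
      flips <- sprintf("%s->LAS", ori)
    }
  }
  dm <- dim(img)
  if (length(dm) > 3L) {
    if (all(dm[-(1:3)] == 1L)) {
      dm <- dm[1:3]
    } else {
      abort(sprintf("'%s' is %dD; a 3D image is required.", path, length(dm)),
        class = "tracheasr_dim_error"
      )
    }
  }
  if (length(dm) != 3L) {
    abort(sprintf("'%s' is %dD; a 3D image is required.", path, length(dm)),
      class = "tracheasr_dim_error"
    )
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (!all(is.finite(sp)) || any(sp <= 0)) {
    abort(sprintf("'%s': missing or non-positive voxel spacing in header.", path),
      class = "tracheasr_metadata_error"
    )
  }
  xf <- RNifti::xform(img)
  org <- if (hdr$qform_code > 0 || hdr$sform_code > 0) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  arr <- array(as.numeric(img), dim = dm)
  list(data = arr, spacing = as.numeric(sp), origin = org, flips = flips)
}

#' Read a binary airway mask from a NIfTI file
#'
#' The image is reoriented to the canonical axes (x left, y anterior,
#' z superior) using its qform/sform; any nonzero label is mapped to
#' foreground. Spacing is taken from the header.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_mask()]; the orientation change applied at load (if any)
#'   is recorded in attribute `"flips"`.
#' @export
read_mask <- function(path) {
  raw <- read_nifti_canonical(path)
  m <- voxel_mask(raw$data != 0, spacing = raw$spacing, origin = raw$origin)
  attr(m, "flips") <- raw$flips
  m
}

#' Read a CT volume (Hounsfield units) from a NIfTI file
#'
#' @inheritParams read_mask
#' @return A [ct_volume()].
#' @export
read_ct <- function(path) {
  raw <- read_nifti_canonical(path)
  v <- ct_volume(raw$data, spacing = raw$spacing, origin = raw$origin)
  attr(v, "flips") <- raw$flips
  v
}

# quaternion (0,1,0) with qfac -1 encodes the LAS canonical frame
canonical_header <- function(spacing, origin) {
  list(
    pixdim = c(-1, spacing, 0, 0, 0, 0),
    qform_code = 1L,
    quatern_b = 0, quatern_c = 1, quatern_d = 0,
    qoffset_x = origin[1], qoffset_y = origin[2], qoffset_z = origin[3]
  )
}

#' Write a mask to a NIfTI file
#'
#' Writes the canonical-orientation mask with spacing and origin in the
#' header, re-loadable by [read_mask()] to an identical object.
#'
#' @param mask A [voxel_mask()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (sum(mask$data) == 0L) {
    warn("Writing a mask with zero foreground voxels.")
  }
  img <- RNifti::asNifti(mask$data,
    reference = canonical_header(mask$spacing, mask$origin)
  )
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint8"),
    error = function(e) {
      abort(sprintf("Cannot write '%s': %s", path, conditionMessage(e)),
        class = "tracheasr_io_error"
      )
    }
  )
  invisible(path)
}

#' Write a CT volume to a NIfTI file
#'
#' @param ct A [ct_volume()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- RNifti::asNifti(ct$data,
    reference = canonical_header(ct$spacing, ct$origin)
  )
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Validate an airway mask for trachea extraction
#'
#' Reports foreground size, 26-connected components, whether the largest
#' component reaches the most superior slices, and per-slice cross-section
#' counts, and flags masks that cannot be analysed.
#'
#' @param mask A [voxel_mask()].
#' @param top_slices Number of most-superior slices in which the largest
#'   component must appear for the mask to be usable (default 10).
#' @param cc Optional precomputed labeling from an earlier stage (internal
#'   reuse); recomputed when `NULL`.
#' @return A list of class `airway_validation`: `n_foreground`,
#'   `n_components`, `largest_component_voxels`, `touches_top`, `usable`,
#'   `reasons` (character), and `per_slice`, a tibble with one row per slice
#'   (`z`, `n_cross_sections`, `area_mm2`).
#' @export
validate_airway_mask <- function(mask, top_slices = 10L, cc = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  nz <- dim(mask$data)[3]
  vox_area <- mask$spacing[1] * mask$spacing[2]
  n_fg <- sum(mask$data)
  reasons <- character(0)
  if (n_fg == 0L) {
    per_slice <- tibble(
      z = seq_len(nz), n_cross_sections = 0L, area_mm2 = 0
    )
    return(structure(
      list(
        n_foreground = 0L, n_components = 0L, largest_component_voxels = 0L,
        touches_top = FALSE, usable = FALSE,
        reasons = "no foreground voxels", per_slice = per_slice
      ),
      class = "airway_validation"
    ))
  }
  cc <- cc %||% label_components_3d(mask$data)
  largest <- which.max(cc$sizes)
  pres <- vapply(seq_len(nz), function(k) largest %in% cc$global[[k]], logical(1))
  top_range <- seq.int(max(1L, nz - top_slices + 1L), nz)
  touches_top <- any(pres[top_range])
  if (!touches_top) {
    reasons <- c(reasons, "no component at superior slices")
  }
  per_slice <- tibble(
    z = seq_len(nz),
    n_cross_sections = vapply(
      seq_len(nz), function(k) max(cc$slice_labels[[k]], 0L), integer(1)
    ),
    area_mm2 = vapply(
      seq_len(nz), function(k) sum(mask$data[, , k]) * vox_area, numeric(1)
    )
  )
  structure(
    list(
      n_foreground = n_fg,
      n_components = length(cc$sizes),
      largest_component_voxels = as.integer(max(cc$sizes)),
      touches_top = touches_top,
      usable = length(reasons) == 0L,
      reasons = reasons,
      per_slice = per_slice
    ),
    class = "airway_validation"
  )
}

#' @export
print.airway_validation <- function(x, ...) {
  cat(sprintf(
    "<airway_validation> %d foreground voxels, %d component(s), usable: %s\n",
    x$n_foreground, x$n_components, x$usable
  ))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}
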