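#' Acquisition geometry and calibration settings
#'
#' Bundles the geometric constants of the multiphoton acquisition: raw and
#' retained field of view, lateral sampling resolution, and the axial depth
#' correction applied because the objective immersion oil (n1 = 1.518) and
#' skin (n2 = 1.37) have different refractive indices, which makes the actual
#' imaging depth half of the apparent (motor) depth. The corrected axial
#' sampling resolution equals the lateral one, giving isotropic 0.5 um voxels.
#'
#' @param fov_raw_um Raw field of view side length in micrometers.
#' @param fov_clipped_um Retained (central) field of view after clipping the
#'   dark invalid frame around the edges.
#' @param lateral_res_um Lateral sampling resolution, um/pixel.
#' @param axial_res_um_actual Actual (corrected) axial sampling resolution,
#'   um/pixel.
#' @param depth_correction_factor Multiplier converting apparent to actual
#'   depth (0.5 for the oil/skin index mismatch).
#' @param n_immersion,n_tissue Refractive indices kept as metadata; the
#'   correction itself is applied through `depth_correction_factor`.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(fov_raw_um = 500, fov_clipped_um = 400,
                               lateral_res_um = 0.5,
                               axial_res_um_actual = 0.5,
                               depth_correction_factor = 0.5,
                               n_immersion = 1.518, n_tissue = 1.37) {
  stopifnot(fov_raw_um > 0, fov_clipped_um > 0,
            fov_clipped_um <= fov_raw_um,
            lateral_res_um > 0, axial_res_um_actual > 0,
            depth_correction_factor > 0)
  structure(list(fov_raw_um = fov_raw_um, fov_clipped_um = fov_clipped_um,
                 lateral_res_um = lateral_res_um,
                 axial_res_um_actual = axial_res_um_actual,
                 depth_correction_factor = depth_correction_factor,
                 n_immersion = n_immersion, n_tissue = n_tissue),
            class = "acquisition_config")
}

#' Construct an image stack
#'
#' A calibrated 3D intensity volume for one imaging channel. Voxels are stored
#' as a numeric array indexed `[z, y, x]`; z index 1 is the first acquired
#' (deepest) plane, x is the stretch axis, and the in-plane angle theta is
#' measured from +x.
#'
#' @param voxels Numeric 3D array `(z, y, x)` of non-negative intensities.
#' @param channel `"collagen"` or `"elastin"`.
#' @param lateral_spacing Lateral voxel spacing, um/pixel.
#' @param axial_spacing_apparent Apparent axial spacing, um/pixel.
#' @param depth_correction_factor Factor converting apparent to actual depth.
#' @param sample_id Free-text sample identifier.
#' @return An object of class `image_stack` with fields `voxels`, `channel`,
#'   spacings (`axial_spacing_actual` is derived) and `sample_id`.
#' @export
image_stack <- function(voxels, channel = c("collagen", "elastin"),
                        lateral_spacing = 0.5, axial_spacing_apparent = 1,
                        depth_correction_factor = 0.5, sample_id = "") {
  channel <- match.arg(channel)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D (z, y, x) array")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  stopifnot(lateral_spacing > 0, axial_spacing_apparent > 0,
            depth_correction_factor > 0)
  structure(list(voxels = voxels, channel = channel,
                 lateral_spacing = lateral_spacing,
                 axial_spacing_apparent = axial_spacing_apparent,
                 axial_spacing_actual =
                   axial_spacing_apparent * depth_correction_factor,
                 depth_correction_factor = depth_correction_factor,
                 sample_id = sample_id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack [%s] %s: %d z-planes of %d x %d px (%.2g um/px lateral, %.2g um/px axial actual)\n",
              x$sample_id, x$channel, d[1], d[2], d[3],
              x$lateral_spacing, x$axial_spacing_actual))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read a multi-page TIFF into an image stack
#'
#' Planes are kept in file order as the z order. All planes must share
#' dimensions.
#'
#' @param path Path to a multi-page TIFF (uint8/uint16).
#' @param channel `"collagen"` or `"elastin"`.
#' @param config An [acquisition_config()].
#' @param sample_id Optional identifier stored in the stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel = c("collagen", "elastin"),
                       config = acquisition_config(), sample_id = "") {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) == 0L) stop("TIFF contains zero planes: ", path)
  dims <- vapply(planes, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged plane dimensions in ", path)
  vox <- array(0, dim = c(length(planes), dims[1, 1], dims[2, 1]))
  for (z in seq_along(planes)) vox[z, , ] <- planes[[z]]
  image_stack(vox, channel = channel,
              lateral_spacing = config$lateral_res_um,
              axial_spacing_apparent =
                config$axial_res_um_actual / config$depth_correction_factor,
              depth_correction_factor = config$depth_correction_factor,
              sample_id = sample_id)
}

#' Write an image stack to a multi-page TIFF
#'
#' Integer intensities up to `2^bits - 1` round-trip exactly through
#' [read_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  scale <- 2^bits - 1
  if (max(stack$voxels) > scale)
    stop("intensities exceed the representable range for ", bits, " bits")
  planes <- lapply(seq_len(dim(stack$voxels)[1]),
                   function(z) stack$voxels[z, , ] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = bits)
  invisible(path)
}

#' Centrally crop a stack to the retained field of view
#'
#' Removes the dark invalid frame around the edges by cropping each plane to
#' `fov_clipped_um` at the lateral resolution (500 x 500 um raw at 0.5 um/px
#' becomes a centered 800 x 800 px crop of the 1000 x 1000 px plane). For odd
#' margins the offset is the floor of the margin, so the crop sits half a
#' pixel toward the origin. The z extent is untouched.
#'
#' @param stack An [image_stack()].
#' @param config An [acquisition_config()].
#' @return The cropped [image_stack()].
#' @export
clip_fov <- function(stack, config = acquisition_config()) {
  stopifnot(inherits(stack, "image_stack"))
  px <- round(config$fov_clipped_um / config$lateral_res_um)
  d <- dim(stack$voxels)
  if (px > d[2] || px > d[3])
    stop(sprintf("requested clip (%d px) exceeds stack extent (%d x %d)",
                 px, d[2], d[3]))
  oy <- (d[2] - px) %/% 2L
  ox <- (d[3] - px) %/% 2L
  out <- stack
  out$voxels <- stack$voxels[, oy + seq_len(px), ox + seq_len(px),
                             drop = FALSE]
  out
}

#' Convert apparent imaging depths to actual depths
#'
#' The refractive-index mismatch between immersion oil and tissue compresses
#' the focal displacement: actual depth = apparent depth x correction factor
#' (0.5 here, i.e. 30 um apparent = 15 um actual).
#'
#' @param apparent_depths Numeric vector of apparent depths, um (>= 0).
#' @param config An [acquisition_config()].
#' @return Actual depths, um.
#' @export
apply_depth_correction <- function(apparent_depths,
                                   config = acquisition_config()) {
  if (any(apparent_depths < 0)) stop("depths must be non-negative")
  apparent_depths * config$depth_correction_factor
}

#' Contrast-limited adaptive histogram equalization, per z-plane
#'
#' Enhances local contrast plane by plane (the volumes are enhanced as 2D
#' images; no 3D equalization is attempted). The output is rescaled back to
#' the input intensity range, so downstream thresholds remain comparable.
#'
#' @param stack An [image_stack()].
#' @param tile_size Side of the contextual tile in pixels (>= 2).
#' @param clip_limit Clip limit as a fraction of the tile histogram (0, 1].
#' @return The enhanced [image_stack()].
#' @export
clahe_enhance <- function(stack, tile_size = 64, clip_limit = 0.01) {
  stopifnot(inherits(stack, "image_stack"), tile_size >= 2,
            clip_limit > 0, clip_limit <= 1)
  d <- dim(stack$voxels)
  if (tile_size > d[2] || tile_size > d[3])
    stop("tile larger than plane")
  rng <- range(stack$voxels)
  out <- stack
  if (rng[2] == rng[1]) return(out)  # constant volume: nothing to equalize
  nx <- max(2L, as.integer(round(d[3] / tile_size)))
  ny <- max(2L, as.integer(round(d[2] / tile_size)))
  bins <- 256L
  for (z in seq_len(d[1])) {
    plane <- (stack$voxels[z, , ] - rng[1]) / (rng[2] - rng[1])
    if (max(plane) == min(plane)) next  # flat plane: leave untouched
    eq <- EBImage::clahe(EBImage::Image(t(plane)), nx = nx, ny = ny,
                         bins = bins, limit = clip_limit * bins)
    out$voxels[z, , ] <- t(EBImage::imageData(eq)) * (rng[2] - rng[1]) + rng[1]
  }
  out
}
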