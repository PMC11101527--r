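#' Binary fiber mask by mean-relative intensity thresholding
#'
#' Thresholds a z-stack at `factor` times its mean intensity (default 0.45)
#' to select fiber voxels. The comparison is strict (`>`) except for the
#' constant-stack edge case, where every voxel equals the mean and the mask
#' is taken as all-true (`>=`) so that a uniformly bright volume counts as
#' full.
#'
#' @param stack An [image_stack()], or a bare numeric 3D array.
#' @param factor Threshold factor relative to the stack mean.
#' @param enhanced If `TRUE`, apply [clahe_enhance()] before thresholding;
#'   default `FALSE` (raw intensities, so the mean is not distorted by the
#'   equalization).
#' @return An object of class `fiber_mask`: logical `mask` (stack shape),
#'   `threshold_value`, `threshold_factor`.
#' @export
binary_mask <- function(stack, factor = 0.45, enhanced = FALSE) {
  if (inherits(stack, "image_stack")) {
    if (enhanced) stack <- clahe_enhance(stack)
    vox <- stack$voxels
  } else {
    vox <- stack
  }
  if (length(vox) == 0L) stop("stack is empty")
  mu <- mean(vox)
  thr <- factor * mu
  if (thr == 0) {
    warning("all-zero stack: threshold 0, empty mask")
    mask <- array(FALSE, dim(vox))
  } else if (min(vox) == max(vox)) {
    mask <- array(vox >= thr, dim(vox))  # constant stack: >= keeps it full
  } else {
    mask <- vox > thr
  }
  structure(list(mask = mask, threshold_value = thr,
                 threshold_factor = factor),
            class = "fiber_mask")
}

#' Fiber density (volume fraction)
#'
#' Fraction of voxels selected by the binary mask: fiber voxel count divided
#' by the total voxel count of the z-stack.
#'
#' @param mask A `fiber_mask` from [binary_mask()], or a logical array.
#' @return Fraction in `[0, 1]`.
#' @export
fiber_density <- function(mask) {
  m <- if (inherits(mask, "fiber_mask")) mask$mask else mask
  if (length(m) == 0L) stop("mask is empty")
  sum(m) / length(m)
}
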