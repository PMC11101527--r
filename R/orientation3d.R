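#' Polar angle from the two out-of-plane projection angles
#'
#' Combines the azimuthal angles of a fiber's projections onto the xz plane
#' (`beta`) and yz plane (`gamma`) into the polar angle phi via
#' `tan^2(phi) = 1/tan^2(beta) + 1/tan^2(gamma)`. Limits: if either
#' projection is flat (`tan = 0`) the fiber is in-plane (phi = 90); if both
#' projections are vertical the fiber runs along z (phi = 0).
#'
#' @param beta,gamma Projection angles in degrees, `[0, 180)`.
#' @return Polar angle phi in degrees, `[0, 90]`. Vectorized.
#' @export
polar_from_projections <- function(beta, gamma) {
  stopifnot(all(beta >= 0 & beta < 180), all(gamma >= 0 & gamma < 180))
  tb <- suppressWarnings(tanpi(beta / 180))
  tg <- suppressWarnings(tanpi(gamma / 180))
  tb[is.nan(tb)] <- Inf  # tanpi(1/2) is NaN by convention; the limit is +-Inf
  tg[is.nan(tg)] <- Inf
  phi <- numeric(length(tb))
  flat <- abs(tb) < 1e-12 | abs(tg) < 1e-12
  phi[flat] <- 90
  if (any(!flat)) {
    t2 <- 1 / tb[!flat]^2 + 1 / tg[!flat]^2
    phi[!flat] <- atan(sqrt(t2)) * 180 / pi
  }
  # tan(90 deg) is +-Inf under tanpi, so 1/tan^2 -> 0 exactly and a fiber
  # vertical in both projections returns phi = 0
  phi
}

#' Construct an orientation field
#'
#' Per-voxel in-plane angle theta (`[0, 180)`, degrees, from the stretch axis
#' x), polar angle phi (degrees; 90 = in-plane), and a validity mask. Arrays
#' share the `(z, y, x)` shape of the source stack.
#'
#' @param theta,phi Numeric 3D arrays (degrees); `NA` where invalid.
#' @param valid Logical 3D array.
#' @param window_size Cubic window size used for estimation (odd, >= 3).
#' @param sampling_ratio Axial-to-lateral sampling ratio (1 for isotropic
#'   voxels).
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(theta, phi, valid, window_size = 11L,
                              sampling_ratio = 1) {
  stopifnot(identical(dim(theta), dim(phi)),
            identical(dim(theta), dim(valid)),
            length(dim(theta)) == 3L,
            window_size >= 3L, window_size %% 2L == 1L)
  structure(list(theta = theta, phi = phi, valid = valid,
                 window_size = as.integer(window_size),
                 sampling_ratio = sampling_ratio),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation_field: %s voxels, %d valid (window %d)\n",
              paste(dim(x$theta), collapse = " x "), sum(x$valid),
              x$window_size))
  invisible(x)
}

#' Estimate voxelwise 3D fiber orientation by weighted vector summation
#'
#' For every voxel brighter than `intensity_threshold_factor` times the stack
#' mean whose cubic window fits inside the volume, the window is
#' max-intensity projected onto the xy, xz and yz planes; in each projection
#' candidate directions (1 degree steps) through the center are weighted by
#' chord length times `max(0, 1 - CV)` of the intensity along the
#' above-threshold run, and the projection angle is the doubled-angle
#' weighted vector sum. The xy angle gives theta; the xz/yz angles combine
#' into phi through [polar_from_projections()]. Border voxels and windows in
#' which every direction has zero weight are marked invalid.
#'
#' @param stack An [image_stack()] with isotropic voxels (rescale anisotropic
#'   stacks upstream).
#' @param window_size Cubic window side in voxels (odd, default 11).
#' @param intensity_threshold_factor Threshold factor applied to the stack
#'   mean intensity (default 0.45, the same rule used for fiber density).
#' @return An [orientation_field()].
#' @export
estimate_orientation <- function(stack, window_size = 11L,
                                 intensity_threshold_factor = 0.45) {
  stopifnot(inherits(stack, "image_stack"),
            window_size >= 3L, window_size %% 2L == 1L)
  d <- dim(stack$voxels)
  if (any(d < window_size))
    stop("stack extents must be >= window_size in all axes")
  thr <- intensity_threshold_factor * mean(stack$voxels)
  if (thr <= 0 || all(stack$voxels <= thr)) {
    warning("no voxels above threshold; returning empty orientation field")
    na <- array(NA_real_, d)
    return(orientation_field(na, na, array(FALSE, d),
                             window_size = window_size))
  }
  res <- .orientation_core(as.numeric(stack$voxels), as.integer(d),
                           thr, as.integer(window_size))
  orientation_field(array(res$theta, d), array(res$phi, d),
                    array(res$valid, d), window_size = window_size)
}

#' Directional summary of an orientation field
#'
#' Center of mass of the axial orientation data and the mean resultant
#' length, i.e. the 3D orientation index (3DOI). With `b_j = |tan(phi_j)|`
#' (equivalently `sqrt(1/tan^2 beta + 1/tan^2 gamma)`):
#' \deqn{\bar C = \frac1n \sum_j \frac{b_j}{\sqrt{1+b_j^2}} \cos 2\theta_j,
#'       \quad
#'       \bar S = \frac1n \sum_j \frac{b_j}{\sqrt{1+b_j^2}} \sin 2\theta_j,
#'       \quad
#'       \bar Z = \frac1n \sum_j \frac{SI_j}{\sqrt{1+b_j^2}},}
#' where `SI = sign(90 - phi)` (and `+1` at `phi = 90`). The 3DOI is
#' `sqrt(C^2 + S^2 + Z^2)` in `[0, 1]`: 0 for strongly disordered, 1 for
#' perfectly aligned fibers. The main in-plane angle is
#' `0.5 * atan2(S, C)` mapped to `[0, 180)`, also reported folded into
#' `[0, 90]` to express the angle to the stretch axis.
#'
#' @param field An [orientation_field()], or a list with numeric `theta`,
#'   `phi` (degrees) and logical `valid` entries of matching length.
#' @return An object of class `directional_summary` with fields `c_bar`,
#'   `s_bar`, `z_bar`, `oi3d`, `main_theta`, `main_theta_folded`, `main_phi`,
#'   `n_valid`.
#' @export
directional_summary <- function(field) {
  th <- field$theta[field$valid]
  ph <- field$phi[field$valid]
  n <- length(th)
  if (n == 0L) stop("orientation field has no valid voxels")
  b <- abs(suppressWarnings(tanpi(ph / 180)))  # NaN only at phi = 90, handled below
  inplane <- ph == 90
  fac <- ifelse(inplane, 1, b / sqrt(1 + b^2))    # b/sqrt(1+b^2) -> 1 as b -> Inf
  zfac <- ifelse(inplane, 0, 1 / sqrt(1 + b^2))
  si <- ifelse(ph == 90, 1, sign(90 - ph))
  th2 <- 2 * th * pi / 180
  c_bar <- mean(fac * cos(th2))
  s_bar <- mean(fac * sin(th2))
  z_bar <- mean(si * zfac)
  oi3d <- sqrt(c_bar^2 + s_bar^2 + z_bar^2)
  main_theta <- 0.5 * atan2(s_bar, c_bar) * 180 / pi
  if (main_theta < 0) main_theta <- main_theta + 180
  if (main_theta >= 180) main_theta <- main_theta - 180
  # main polar angle of the mass center: planar component vs z component
  main_phi <- atan2(sqrt(c_bar^2 + s_bar^2), z_bar) * 180 / pi
  structure(list(c_bar = c_bar, s_bar = s_bar, z_bar = z_bar,
                 oi3d = min(oi3d, 1), main_theta = main_theta,
                 main_theta_folded = fold_angle(main_theta),
                 main_phi = main_phi, n_valid = n),
            class = "directional_summary")
}

#' @export
print.directional_summary <- function(x, ...) {
  cat(sprintf(
    "directional_summary: 3DOI = %.4f, main theta = %.1f deg (folded %.1f), n = %d\n",
    x$oi3d, x$main_theta, x$main_theta_folded, x$n_valid))
  invisible(x)
}

#' Fold an in-plane angle onto the stretch half-quadrant
#'
#' Maps theta in `[0, 180)` to `[0, 90]` by reflecting angles above 90
#' degrees (`180 - theta`), expressing the angle between the fiber and the
#' stretch axis regardless of side.
#'
#' @param theta Degrees in `[0, 180)`. Vectorized.
#' @return Degrees in `[0, 90]`.
#' @export
fold_angle <- function(theta) {
  if (any(theta < 0 | theta >= 180)) stop("theta must lie in [0, 180)")
  ifelse(theta > 90, 180 - theta, theta)
}

#' Per-layer in-plane angle histograms
#'
#' One-degree binning of theta over `(0, 180]` (an estimate of exactly 0 is
#' axially identical to 180 and counted there), normalized per z-layer, plus
#' the aggregate distribution over all layers. Layers without valid voxels
#' yield zero rows and are flagged.
#'
#' @param field An [orientation_field()].
#' @return An object of class `angular_histogram`: `bin_edges` (0..180),
#'   `bin_centers`, `per_layer` (layers x 180 matrix of frequencies summing
#'   to 1 per nonempty row), `aggregate` (length-180, sums to 1),
#'   `empty_layers` (indices).
#' @export
layer_histograms <- function(field) {
  d <- dim(field$theta)
  nz <- d[1]
  per_layer <- matrix(0, nrow = nz, ncol = 180)
  counts <- matrix(0, nrow = nz, ncol = 180)
  for (z in seq_len(nz)) {
    th <- field$theta[z, , ][field$valid[z, , ]]
    if (length(th) == 0L) next
    bin <- ceiling(th)          # (d-1, d] -> bin d
    bin[bin == 0L] <- 180L      # theta == 0 counts as 180 (axial identity)
    tab <- tabulate(bin, nbins = 180)
    counts[z, ] <- tab
    per_layer[z, ] <- tab / sum(tab)
  }
  empty <- which(rowSums(counts) == 0)
  if (length(empty) > 0 && length(empty) == nz)
    stop("orientation field has no valid voxels in any layer")
  total <- colSums(counts)
  structure(list(bin_edges = 0:180, bin_centers = (1:180) - 0.5,
                 per_layer = per_layer, aggregate = total / sum(total),
                 empty_layers = empty),
            class = "angular_histogram")
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("angular_histogram: %d layers x 180 one-degree bins (%d empty layers)\n",
              nrow(x$per_layer), length(x$empty_layers)))
  invisible(x)
}
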