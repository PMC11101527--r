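#' Specification of a synthetic fiber phantom
#'
#' Describes a 3D volume of straight tubular fibers whose in-plane angles
#' follow a two-family axial von Mises mixture (the structure observed in
#' dermal collagen: two families near 45 and 135 degrees) and whose polar
#' angles concentrate around 90 degrees (in-plane, as in thin imaging
#' volumes).
#'
#' @param shape Integer `(z, y, x)` extents.
#' @param theta_mixture A [vm_mixture()] with `b = 0` for the in-plane
#'   angles. Default: the two-family pattern with means 45/135 degrees.
#' @param phi_concentration Axial von Mises concentration of phi around 90
#'   degrees (larger = flatter fibers). Default 20.
#' @param fiber_radius_px Cylinder radius in pixels (>= 1).
#' @param target_fill Target fiber volume fraction in `(0, 0.9)`.
#' @param fiber_intensity,background_intensity Intensity levels.
#' @param noise_sd Additive Gaussian noise SD (clamped at 0).
#' @param seed Integer seed.
#' @return An object of class `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(shape = c(30L, 128L, 128L),
                               theta_mixture = vm_mixture(w = 0.5,
                                                          alpha1 = 45, a1 = 2,
                                                          alpha2 = 135, a2 = 2),
                               phi_concentration = 20,
                               fiber_radius_px = 2,
                               target_fill = 0.4,
                               fiber_intensity = 200,
                               background_intensity = 10,
                               noise_sd = 5,
                               seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            inherits(theta_mixture, "vm_mixture"), theta_mixture$b == 0,
            target_fill > 0, target_fill < 0.9,
            fiber_radius_px >= 1,
            fiber_intensity >= 0, background_intensity >= 0, noise_sd >= 0)
  structure(list(shape = as.integer(shape), theta_mixture = theta_mixture,
                 phi_concentration = phi_concentration,
                 fiber_radius_px = fiber_radius_px,
                 target_fill = target_fill,
                 fiber_intensity = fiber_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fiber_phantom_spec")
}

#' Generate a fiber phantom stack with known ground truth
#'
#' Repeatedly draws a fiber orientation (theta from the mixture, phi from an
#' axial von Mises concentrated at 90 degrees), a uniform anchor point, and
#' rasterizes a straight cylinder of the requested radius clipped to the
#' volume, until the fill fraction reaches the target (or an iteration cap).
#' Overlapping fibers take the maximum intensity; Gaussian noise is added
#' and clamped at zero.
#'
#' @param spec A [fiber_phantom_spec()].
#' @param channel Channel label for the returned stack.
#' @return A list: `stack` ([image_stack()]), `truth` (data frame of per-fiber
#'   `theta`, `phi`), `labels` (integer array; fiber id per voxel, overlaps
#'   keep the last id), `fill` (achieved fraction).
#' @export
gen_fiber_stack <- function(spec, channel = "collagen") {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  vol <- array(spec$background_intensity, d)
  labels <- array(0L, d)
  nvox <- prod(d)
  target_vox <- spec$target_fill * nvox
  r <- spec$fiber_radius_px

  # precompute ball offsets for stamping along the centerline
  rg <- -ceiling(r):ceiling(r)
  ball <- expand.grid(dz = rg, dy = rg, dx = rg)
  ball <- ball[ball$dz^2 + ball$dy^2 + ball$dx^2 <= r^2, ]

  fibers <- list()
  n_on <- 0L
  iter <- 0L
  max_iter <- 10000L
  while (n_on < target_vox && iter < max_iter) {
    iter <- iter + 1L
    theta <- vm_sample(spec$theta_mixture, 1L)
    phi <- .rvonmises(1L, pi, spec$phi_concentration) / 2 * 180 / pi
    phi <- phi %% 180
    thr <- theta * pi / 180
    phr <- phi * pi / 180
    # direction in (x, y, z); x = stretch axis
    u <- c(sin(phr) * cos(thr), sin(phr) * sin(thr), cos(phr))
    anchor <- c(stats::runif(1, 1, d[3]), stats::runif(1, 1, d[2]),
                stats::runif(1, 1, d[1]))  # (x, y, z)
    # param range of the centerline inside the bounding box
    tlim <- c(-Inf, Inf)
    ext <- c(d[3], d[2], d[1])
    for (ax in 1:3) {
      if (abs(u[ax]) > 1e-9) {
        t1 <- (1 - anchor[ax]) / u[ax]
        t2 <- (ext[ax] - anchor[ax]) / u[ax]
        tlim <- c(max(tlim[1], min(t1, t2)), min(tlim[2], max(t1, t2)))
      }
    }
    if (!is.finite(tlim[1])) tlim[1] <- -max(ext)
    if (!is.finite(tlim[2])) tlim[2] <- max(ext)
    if (tlim[2] <= tlim[1]) next
    ts <- seq(tlim[1], tlim[2], by = 0.5)
    cx <- round(anchor[1] + ts * u[1])
    cy <- round(anchor[2] + ts * u[2])
    cz <- round(anchor[3] + ts * u[3])
    keep <- !duplicated(cbind(cz, cy, cx))
    cx <- cx[keep]; cy <- cy[keep]; cz <- cz[keep]
    if (length(cx) == 0L) next
    # stamp the ball at each centerline voxel
    vz <- rep(cz, each = nrow(ball)) + ball$dz
    vy <- rep(cy, each = nrow(ball)) + ball$dy
    vx <- rep(cx, each = nrow(ball)) + ball$dx
    ok <- vz >= 1 & vz <= d[1] & vy >= 1 & vy <= d[2] & vx >= 1 & vx <= d[3]
    if (!any(ok)) next
    idx <- unique(vz[ok] + d[1] * ((vy[ok] - 1) + d[2] * (vx[ok] - 1)))
    fresh <- labels[idx] == 0L
    fid <- length(fibers) + 1L
    fibers[[fid]] <- c(theta = theta, phi = phi)
    labels[idx] <- fid
    vol[idx] <- pmax(vol[idx], spec$fiber_intensity)
    n_on <- n_on + sum(fresh)
  }
  if (n_on < target_vox)
    warning("iteration cap reached before target fill; achieved ",
            round(n_on / nvox, 3))
  if (spec$noise_sd > 0)
    vol <- array(pmax(0, vol + stats::rnorm(nvox, 0, spec$noise_sd)), d)
  truth <- do.call(rbind, lapply(fibers, function(f)
    data.frame(theta = f[["theta"]], phi = f[["phi"]])))
  list(stack = image_stack(vol, channel = channel,
                           lateral_spacing = 0.5,
                           axial_spacing_apparent = 1,
                           depth_correction_factor = 0.5,
                           sample_id = "phantom"),
       truth = truth, labels = labels, fill = n_on / nvox)
}

#' Specification of a synthetic J-shaped stress-strain curve
#'
#' @param E1_nominal Toe-region modulus, MPa.
#' @param E2_nominal Linear-region modulus, MPa (> E1).
#' @param sigma_max_nominal Stress at maximum strain, MPa; `NA` to leave the
#'   curve unscaled.
#' @param eps_max_nominal Maximum strain.
#' @param heel_center,heel_width Center and width (strain units) of the
#'   logistic toe-to-linear transition; `heel_center < eps_max`.
#' @param n_points Samples along the curve.
#' @param noise_sd Additive stress noise SD, MPa.
#' @param seed Integer seed.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(E1_nominal = 0.1, E2_nominal = 20,
                       sigma_max_nominal = 4, eps_max_nominal = 0.4,
                       heel_center = 0.25, heel_width = 0.015,
                       n_points = 400L, noise_sd = 0.01, seed = 1L) {
  stopifnot(E1_nominal > 0, E2_nominal > E1_nominal || E2_nominal == E1_nominal,
            eps_max_nominal > 0, heel_center < eps_max_nominal,
            heel_width > 0, n_points >= 20L, noise_sd >= 0)
  structure(list(E1_nominal = E1_nominal, E2_nominal = E2_nominal,
                 sigma_max_nominal = sigma_max_nominal,
                 eps_max_nominal = eps_max_nominal,
                 heel_center = heel_center, heel_width = heel_width,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "curve_spec")
}

# noiseless generator stress at strain eps (before scaling): the integral of
# a logistic stiffness switch E(e) = E1 + (E2 - E1) * logistic((e - c)/width),
# i.e. sigma(e) = E1*e + (E2 - E1) * width * (softplus((e-c)/w) - softplus(-c/w)).
# In the width -> 0 limit this is exactly E1*e + (E2 - E1)*max(0, e - c),
# and the stress is monotone with slope between E1 and E2 everywhere.
.curve_sigma_raw <- function(eps, spec) {
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  w <- spec$heel_width
  c0 <- spec$heel_center
  spec$E1_nominal * eps +
    (spec$E2_nominal - spec$E1_nominal) * w *
      (softplus((eps - c0) / w) - softplus(-c0 / w))
}

#' Generate a synthetic J-shaped stress-strain curve with known truth
#'
#' The noiseless generator integrates a logistic stiffness switch: the
#' tangent modulus is `E1 + (E2 - E1) * logistic((eps - heel_center) /
#' heel_width)`, so `sigma(eps) = E1*eps + (E2 - E1) * heel_width *
#' (softplus((eps - heel_center)/heel_width) - softplus(-heel_center/
#' heel_width))`. In the `heel_width -> 0` limit this is the sharp
#' piecewise-linear J-curve `E1*eps + (E2 - E1)*max(0, eps - heel_center)`,
#' and stress is monotone with slope between `E1` and `E2` everywhere. The
#' curve is truncated at `eps_max` and, when `sigma_max_nominal` is given, scaled so
#' that `sigma(eps_max) = sigma_max_nominal` (the scaling multiplies the
#' effective moduli, and the returned nominal characteristics account for
#' it). Gaussian noise is added on top. Nominal `eps_mid` is solved on the
#' noiseless curve by root finding.
#'
#' @param spec A [curve_spec()].
#' @param geometry A [sample_geometry()] recorded in the curve.
#' @return A list: `curve` (a `stress_strain_curve`), `nominal` (a
#'   `mech_characteristics` computed analytically from the scaled noiseless
#'   generator), `scale` (the applied stress scale factor).
#' @export
gen_stress_strain <- function(spec, geometry = sample_geometry()) {
  stopifnot(inherits(spec, "curve_spec"))
  set.seed(spec$seed)
  eps <- seq(0, spec$eps_max_nominal, length.out = spec$n_points)
  sig <- .curve_sigma_raw(eps, spec)
  smax_raw <- sig[spec$n_points]
  scale <- if (is.na(spec$sigma_max_nominal)) 1 else {
    if (smax_raw <= 0) stop("inconsistent spec: sigma_max unreachable")
    spec$sigma_max_nominal / smax_raw
  }
  sig <- sig * scale
  sigma_max <- sig[spec$n_points]
  half <- 0.5 * sigma_max
  eps_mid <- stats::uniroot(function(e) .curve_sigma_raw(e, spec) * scale - half,
                            c(0, spec$eps_max_nominal))$root
  nominal <- structure(list(
    E1 = spec$E1_nominal * scale, E2 = spec$E2_nominal * scale,
    sigma_max = sigma_max, eps_max = spec$eps_max_nominal,
    eps_mid = eps_mid,
    toe_end = NA_real_, linear_start = NA_real_, linear_end = NA_real_,
    fit_r2_linear = NA_real_, flags = character(0)),
    class = "mech_characteristics")
  noisy <- sig + stats::rnorm(spec$n_points, 0, spec$noise_sd)
  noisy[1] <- 0
  curve <- structure(list(strain = eps, stress = noisy, geometry = geometry,
                          speed_mm_per_s = 0.5),
                     class = "stress_strain_curve")
  list(curve = curve, nominal = nominal, scale = scale)
}

#' Generate a synthetic cohort feature table with planted dependencies
#'
#' Draws base features from realistic marginals (ages skewed elderly,
#' moduli, densities and orientation indices in the observed cohort ranges),
#' then overwrites targets of the dependency specification with
#' `link(source) + noise`. Optionally blanks cells to mimic cohort
#' missingness: 3 rows missing `E1` and 2 different rows missing the whole
#' elastin block, so complete-case filtering of a 24-row table keeps 19.
#'
#' @param n_samples Number of rows (default 24).
#' @param dependency_spec List of planted links, each a list with elements
#'   `target` (column name), `source` (column name), `link` (function), and
#'   `noise_sd`. Targets must not feed back into their own sources
#'   (acyclic).
#' @param missingness `TRUE` (default) to blank 3 `E1` cells and 2 elastin
#'   blocks (disjoint rows).
#' @param seed Integer seed.
#' @return A list: `table` (data frame with the cohort feature schema),
#'   `adjacency` (logical matrix of planted links, symmetric).
#' @export
gen_cohort <- function(n_samples = 24L, dependency_spec = list(),
                       missingness = TRUE, seed = 1L) {
  set.seed(seed)
  n <- n_samples
  tab <- data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    age = round(stats::runif(n, 61, 95)),
    E1 = stats::rlnorm(n, log(0.1), 0.4),
    E2 = stats::rlnorm(n, log(20), 0.5),
    sigma_max = stats::rlnorm(n, log(3.9), 0.5),
    eps_max = stats::runif(n, 0.25, 0.5),
    eps_mid = stats::runif(n, 0.18, 0.46),
    D_CO = stats::runif(n, 0.3, 0.7),
    T_CO = stats::runif(n, 16.7, 111.8),
    OI3D_CO = stats::runif(n, 0.06, 0.25),
    main_theta_CO = stats::runif(n, 27, 49.5),
    D_EL = stats::runif(n, 0.002, 0.45),
    T_EL = stats::runif(n, 2.58, 5.09),
    OI3D_EL = stats::runif(n, 0.01, 0.24),
    main_theta_EL = stats::runif(n, 10, 90),
    stringsAsFactors = FALSE)

  # cycle check on the planted links
  if (length(dependency_spec) > 0) {
    edges <- vapply(dependency_spec,
                    function(l) c(l$source, l$target), character(2))
    nodes <- unique(as.vector(edges))
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (k in seq_len(ncol(edges))) adj[edges[1, k], edges[2, k]] <- TRUE
    rem <- nodes
    repeat {
      sinkless <- rem[colSums(adj[rem, rem, drop = FALSE]) == 0]
      if (length(sinkless) == 0) {
        if (length(rem) > 0) stop("cyclic dependency spec")
        break
      }
      rem <- setdiff(rem, sinkless)
      if (length(rem) == 0) break
    }
  }
  for (l in dependency_spec) {
    stopifnot(l$target %in% names(tab), l$source %in% names(tab))
    tab[[l$target]] <- l$link(tab[[l$source]]) +
      stats::rnorm(n, 0, l$noise_sd)
  }

  feats <- setdiff(names(tab), "sample_id")
  adjacency <- matrix(FALSE, length(feats), length(feats),
                      dimnames = list(feats, feats))
  for (l in dependency_spec) {
    adjacency[l$source, l$target] <- TRUE
    adjacency[l$target, l$source] <- TRUE
  }

  if (missingness && n >= 5L) {
    rows <- sample.int(n, 5L)
    tab$E1[rows[1:3]] <- NA
    for (col in c("D_EL", "T_EL", "OI3D_EL", "main_theta_EL"))
      tab[[col]][rows[4:5]] <- NA
  }
  list(table = tab, adjacency = adjacency)
}
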