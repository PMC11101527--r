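#' Tensile specimen geometry
#'
#' Initial dimensions of the dog-bone tensile specimen. Defaults follow the
#' standard preparation: 40 mm length, 20 mm width, 0.8 mm thickness.
#'
#' @param L0 Initial length, mm.
#' @param w0 Initial width, mm.
#' @param e0 Initial thickness, mm.
#' @return An object of class `sample_geometry`.
#' @export
sample_geometry <- function(L0 = 40, w0 = 20, e0 = 0.8) {
  stopifnot(L0 > 0, w0 > 0, e0 > 0)
  structure(list(L0 = L0, w0 = w0, e0 = e0), class = "sample_geometry")
}

#' Build a stress-strain curve from a tensile log
#'
#' Engineering strain `eps = dL / L0` and nominal stress
#' `sigma = F / (w0 * e0)`; with mm and N this is N/mm^2 = MPa directly. A
#' light moving-average smoothing (window 1% of the record, minimum 3
#' points) is applied to the force channel before conversion to damp sensor
#' noise.
#'
#' @param displacement_mm Motor displacement `dL`, mm.
#' @param force_N Measured force, N (same length).
#' @param geometry A [sample_geometry()].
#' @param speed_mm_per_s Loading speed recorded as metadata (default 0.5).
#' @param smooth Apply the force smoothing (default `TRUE`).
#' @return An object of class `stress_strain_curve`: numeric `strain`
#'   (unitless), `stress` (MPa), plus `geometry` and `speed_mm_per_s`.
#' @export
build_curve <- function(displacement_mm, force_N,
                        geometry = sample_geometry(),
                        speed_mm_per_s = 0.5, smooth = TRUE) {
  if (length(displacement_mm) != length(force_N))
    stop("displacement and force must have equal length")
  n <- length(force_N)
  if (n < 10L) stop("need at least 10 samples for a curve")
  if (any(force_N < -0.05 * max(abs(force_N))))
    stop("negative forces beyond tolerance")
  f <- force_N
  if (smooth) {
    w <- max(3L, round(0.01 * n))
    if (w %% 2L == 0L) w <- w + 1L
    sm <- stats::filter(f, rep(1 / w, w), sides = 2)
    f <- ifelse(is.na(sm), f, as.numeric(sm))  # keep raw values at the ends
  }
  structure(list(strain = displacement_mm / geometry$L0,
                 stress = f / (geometry$w0 * geometry$e0),
                 geometry = geometry, speed_mm_per_s = speed_mm_per_s),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf(
    "stress_strain_curve: %d points, strain %.3f..%.3f, stress %.3g..%.3g MPa\n",
    length(x$strain), min(x$strain), max(x$strain),
    min(x$stress), max(x$stress)))
  invisible(x)
}

#' Upper envelope of a stepwise-loading curve
#'
#' Stepwise stretching protocols pause the motors for imaging, and stress
#' relaxes during the pauses, leaving drops in the recorded curve. The
#' running maximum of stress over strain recovers the loading envelope that
#' the continuous protocol would have traced; continuous curves pass through
#' unchanged.
#'
#' @param curve A [build_curve()] result.
#' @return A `stress_strain_curve` with non-decreasing stress.
#' @export
upper_envelope <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  ord <- order(curve$strain)
  out <- curve
  out$strain <- curve$strain[ord]
  out$stress <- cummax(curve$stress[ord])
  out
}

# pointwise local linearity: R^2 of the moving-window straight-line fit
# (half-width h points) at every index. A curve is "locally linear" at a
# point when this R^2 clears the threshold; the linear region is the
# maximal contiguous run of such points containing the anchor. Checking the
# R^2 of the whole candidate window instead would admit windows spanning
# the heel and toe, because the steep branch dominates the total variance.
.local_r2 <- function(eps, sig, h) {
  n <- length(eps)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    x <- eps[lo:hi]; y <- sig[lo:hi]
    if (stats::sd(x) == 0) return(0)
    if (stats::sd(y) == 0) return(1)  # exactly flat is exactly linear
    r <- stats::cor(x, y)
    if (is.na(r)) 0 else r^2
  }, numeric(1))
}

#' Segment a stress-strain curve into toe, heel and linear regions
#'
#' The toe region runs from zero strain to the first strain where stress
#' exceeds `toe_frac` of the maximum stress (default 5%). The linear region
#' is the widest contiguous strain window containing the point of maximum
#' local slope throughout which the curve is locally linear: every point in
#' the window must have a moving-window straight-line fit (half-width 2.5%
#' of the record) with `R^2 >= r2_min` (default 0.99). The pointwise
#' criterion matters: judging the whole window by a single R^2 would let it
#' swallow the heel and toe, whose misfit is masked by the steep branch's
#' variance. The heel is whatever lies between toe and linear region. Both
#' thresholds are exposed because the segmentation rule is a package
#' convention: published curves mark the regions by eye.
#'
#' @param curve A [build_curve()] result (apply [upper_envelope()] first for
#'   stepwise-loading records).
#' @param r2_min Minimum R^2 of the linear-region fit.
#' @param toe_frac Stress fraction of `sigma_max` ending the toe region.
#' @return A list with strains `toe_end`, `linear_start`, `linear_end`,
#'   index window `linear_idx`, and `fit_r2_linear`.
#' @export
segment_regions <- function(curve, r2_min = 0.99, toe_frac = 0.05) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  ord <- order(curve$strain)
  eps <- curve$strain[ord]
  sig <- curve$stress[ord]
  imax <- which.max(sig)
  smax <- sig[imax]
  if (smax <= 0) stop("degenerate flat curve: no positive stress")
  eps <- eps[1:imax]
  sig <- sig[1:imax]
  n <- length(eps)
  itoe <- which(sig > toe_frac * smax)[1]
  toe_end <- if (is.na(itoe)) eps[n] else eps[itoe]
  # local slope on a coarse grid to anchor the linear window
  k <- max(2L, round(n / 50))
  slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    if (eps[hi] > eps[lo]) slope[i] <- (sig[hi] - sig[lo]) / (eps[hi] - eps[lo])
  }
  h <- max(3L, round(0.025 * n))
  ok <- .local_r2(eps, sig, h) >= r2_min
  # anchor on the steepest locally linear point; truncated boundary windows
  # and kinks (e.g. envelope re-joins) are not locally linear and would
  # otherwise trap the window at a single index
  anchor <- if (any(ok)) which(ok)[which.max(slope[ok])] else which.max(slope)
  lo <- anchor
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- anchor
  while (hi < n && ok[hi + 1L]) hi <- hi + 1L
  win <- c(lo, hi)
  x <- eps[lo:hi]; y <- sig[lo:hi]
  r2 <- if (length(x) > 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y)^2 else 1
  linear_start <- max(eps[win[1]], toe_end)
  list(toe_end = toe_end,
       linear_start = linear_start,
       linear_end = eps[win[2]],
       linear_idx = win,
       fit_r2_linear = r2)
}

#' Extract the five mechanical characteristics of a stress-strain curve
#'
#' The descriptors of the J-shaped tensile response: initial modulus `E1`
#' (least-squares slope over the toe region), elastic modulus `E2` (slope
#' over the linear region), maximum stress `sigma_max`, strain at maximum
#' stress `eps_max`, and midpoint strain `eps_mid`, the linearly
#' interpolated strain at which stress first crosses half of `sigma_max`.
#'
#' @param curve A [build_curve()] result.
#' @param envelope Apply [upper_envelope()] first (`TRUE` for
#'   stepwise-loading records; default `FALSE`).
#' @param r2_min,toe_frac Segmentation parameters, see [segment_regions()].
#' @return An object of class `mech_characteristics` with fields `E1`, `E2`
#'   (MPa), `sigma_max` (MPa), `eps_max`, `eps_mid`, `toe_end`,
#'   `linear_start`, `linear_end`, `fit_r2_linear`, and `flags` (character;
#'   e.g. non-monotone stress around the midpoint crossing).
#' @export
extract_characteristics <- function(curve, envelope = FALSE,
                                    r2_min = 0.99, toe_frac = 0.05) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (envelope) curve <- upper_envelope(curve)
  seg <- segment_regions(curve, r2_min = r2_min, toe_frac = toe_frac)
  ord <- order(curve$strain)
  eps <- curve$strain[ord]
  sig <- curve$stress[ord]
  imax <- which.max(sig)
  sigma_max <- sig[imax]
  eps_max <- eps[imax]
  flags <- character(0)

  slope_fit <- function(idx) {
    if (length(idx) < 2L || stats::sd(eps[idx]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(sig[idx] ~ eps[idx]))[2])
  }
  toe_idx <- which(eps <= seg$toe_end)
  if (length(toe_idx) < 2L) toe_idx <- 1:2
  E1 <- slope_fit(toe_idx)
  E2 <- slope_fit(seg$linear_idx[1]:seg$linear_idx[2])

  half <- 0.5 * sigma_max
  cross <- which(sig[1:imax] >= half)[1]
  if (is.na(cross)) {
    eps_mid <- NA_real_
    flags <- c(flags, "no midpoint crossing")
  } else if (cross == 1L) {
    eps_mid <- eps[1]
  } else {
    e0 <- eps[cross - 1]; e1 <- eps[cross]
    s0 <- sig[cross - 1]; s1 <- sig[cross]
    eps_mid <- if (s1 > s0) e0 + (half - s0) / (s1 - s0) * (e1 - e0) else e1
    if (any(diff(sig[1:imax]) < 0))
      flags <- c(flags, "non-monotone stress; first crossing taken")
  }
  structure(list(E1 = E1, E2 = E2, sigma_max = sigma_max, eps_max = eps_max,
                 eps_mid = eps_mid, toe_end = seg$toe_end,
                 linear_start = seg$linear_start,
                 linear_end = seg$linear_end,
                 fit_r2_linear = seg$fit_r2_linear, flags = flags),
            class = "mech_characteristics")
}

#' @export
print.mech_characteristics <- function(x, ...) {
  cat(sprintf(
    "mech_characteristics: E1 = %.3g MPa, E2 = %.3g MPa, sigma_max = %.3g MPa, eps_max = %.3g, eps_mid = %.3g\n",
    x$E1, x$E2, x$sigma_max, x$eps_max, x$eps_mid))
  cat(sprintf("  regions: toe <= %.3g, linear %.3g..%.3g (R^2 = %.4f)\n",
              x$toe_end, x$linear_start, x$linear_end, x$fit_r2_linear))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.mech_characteristics <- function(object, ...) {
  c(E1 = object$E1, E2 = object$E2, sigma_max = object$sigma_max,
    eps_max = object$eps_max, eps_mid = object$eps_mid)
}

#' Classify a sample by midpoint strain
#'
#' Cohort curves split into a low midpoint-strain group (`eps_mid < cut`)
#' and a high group (`eps_mid >= cut`), with the conventional cut at 0.27.
#'
#' @param eps_mid Midpoint strain(s).
#' @param cut Group boundary (default 0.27).
#' @return Factor with levels `"low"` and `"high"`.
#' @export
midpoint_group <- function(eps_mid, cut = 0.27) {
  factor(ifelse(eps_mid < cut, "low", "high"), levels = c("low", "high"))
}
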