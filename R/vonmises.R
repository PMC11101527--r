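#' Two-component axial von Mises mixture parameters
#'
#' Parameter record of the axial (pi-periodic) two-family von Mises mixture
#' used to model in-plane fiber angle distributions:
#' \deqn{\rho(\theta) = b + w\,\frac{e^{a_1\cos 2(\theta-\alpha_1)}}{\pi I_0(a_1)}
#'   + (1-w)\,\frac{e^{a_2\cos 2(\theta-\alpha_2)}}{\pi I_0(a_2)},}
#' with `b` a constant offset, `w` the weight of the first fiber family,
#' `alpha1`/`alpha2` the mean fiber angles (degrees) and `a1`/`a2` the
#' concentration parameters; `I_0` is the modified Bessel function of order
#' zero. With `b = 0` the density integrates to 1 over `[0, pi)`.
#'
#' @param w Weight of the first family, in `[0, 1]`.
#' @param alpha1,alpha2 Mean fiber angles, degrees in `[0, 180)`.
#' @param a1,a2 Concentration parameters, `>= 0`.
#' @param b Constant offset (per-radian density units), `>= 0`.
#' @param order If `TRUE` (default) relabel families so `alpha1 <= alpha2`.
#' @return An object of class `vm_mixture`.
#' @export
vm_mixture <- function(w, alpha1, a1, alpha2, a2, b = 0, order = TRUE) {
  stopifnot(w >= 0, w <= 1, a1 >= 0, a2 >= 0, b >= 0,
            alpha1 >= 0, alpha1 < 180, alpha2 >= 0, alpha2 < 180)
  if (order && alpha1 > alpha2) {
    tmp <- list(w = 1 - w, alpha1 = alpha2, a1 = a2, alpha2 = alpha1, a2 = a1)
    w <- tmp$w; alpha1 <- tmp$alpha1; a1 <- tmp$a1
    alpha2 <- tmp$alpha2; a2 <- tmp$a2
  }
  structure(list(b = b, w = w, alpha1 = alpha1, a1 = a1,
                 alpha2 = alpha2, a2 = a2),
            class = "vm_mixture")
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat(sprintf(
    "vm_mixture: w = %.3f | family 1: alpha = %.2f deg, a = %.3f | family 2: alpha = %.2f deg, a = %.3f | b = %.4f\n",
    x$w, x$alpha1, x$a1, x$alpha2, x$a2, x$b))
  invisible(x)
}

# exp(a cos x) / I0(a), numerically stable for large a via the
# exponentially scaled Bessel function
.vm_kernel <- function(x, a) {
  exp(a * (cos(x) - 1)) / besselI(a, 0, expon.scaled = TRUE)
}

#' Axial von Mises mixture density
#'
#' Evaluates the two-family mixture density (per radian, pi-periodic in
#' theta).
#'
#' @param theta Angles in degrees (any real values; the density is
#'   180-degree periodic).
#' @param params A [vm_mixture()].
#' @return Density values, per radian.
#' @export
vm_density <- function(theta, params) {
  stopifnot(inherits(params, "vm_mixture"))
  th <- theta * pi / 180
  a1r <- params$alpha1 * pi / 180
  a2r <- params$alpha2 * pi / 180
  params$b +
    params$w / pi * .vm_kernel(2 * (th - a1r), params$a1) +
    (1 - params$w) / pi * .vm_kernel(2 * (th - a2r), params$a2)
}

# one axial von Mises draw set: sample 2*theta from von Mises(2*alpha, a)
# with the Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler,
# then halve and wrap into (0, 180]
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Sample axial fiber angles from a von Mises mixture
#'
#' Draws the family label per Bernoulli(`w`), samples `2*theta` from the
#' circular von Mises distribution with mean `2*alpha` and the family's
#' concentration, halves and wraps into `(0, 180]`. Requires the normalized
#' mixture (`b = 0`).
#'
#' @param params A [vm_mixture()] with `b = 0`.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Angles in degrees, `(0, 180]`.
#' @export
vm_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "vm_mixture"), n >= 1)
  if (params$b != 0)
    stop("sampling is defined for the normalized mixture (b = 0)")
  if (!is.null(seed)) set.seed(seed)
  fam1 <- stats::runif(n) < params$w
  n1 <- sum(fam1)
  th <- numeric(n)
  if (n1 > 0)
    th[fam1] <- .rvonmises(n1, 2 * params$alpha1 * pi / 180, params$a1) / 2
  if (n1 < n)
    th[!fam1] <- .rvonmises(n - n1, 2 * params$alpha2 * pi / 180, params$a2) / 2
  deg <- th * 180 / pi
  deg <- deg %% 180
  deg[deg == 0] <- 180
  deg
}

# circularly smoothed histogram peaks (axial, 180 bins) for initialization
.vm_peak_starts <- function(dens, centers) {
  k <- 7L  # smoothing half-width, degrees
  n <- length(dens)
  sm <- vapply(seq_len(n), function(i) {
    idx <- ((i - k - 1):(i + k - 1)) %% n + 1
    mean(dens[idx])
  }, numeric(1))
  p1 <- which.max(sm)
  # suppress a 40-degree neighbourhood (circular) around the first peak
  dist <- pmin(abs(seq_len(n) - p1), n - abs(seq_len(n) - p1))
  sm2 <- sm
  sm2[dist < 40] <- -Inf
  p2 <- which.max(sm2)
  if (!is.finite(sm2[p2])) p2 <- (p1 + 90 - 1) %% n + 1
  c(centers[p1], centers[p2])
}

#' Fit a two-family axial von Mises mixture to an angle histogram
#'
#' Least-squares fit of [vm_density()] at the histogram bin centers to the
#' binned distribution (converted to per-radian density units). The
#' optimizer is bounded (`b` in `[0, 1]`, `w` in `[0, 1]`, concentrations in
#' `[0, 100]`) and multi-started from the two highest circularly smoothed
#' histogram peaks plus the swapped assignment; the lowest-RSS solution is
#' returned with families ordered by mean angle. A fit is flagged
#' `degenerate` when the second family collapses (weight near 0 or 1, or the
#' two mean angles nearly coincide) — mirroring histograms where one family
#' is hard to determine.
#'
#' @param hist An `angular_histogram` (its `aggregate` slot is used), or a
#'   numeric vector of 180 normalized one-degree frequencies.
#' @return An object of class `vm_fit`: `params` ([vm_mixture()]), `rss`,
#'   `converged`, `degenerate`, `fitted` (density at bin centers),
#'   `bin_centers`, `density` (observed, per radian).
#' @export
vm_fit <- function(hist) {
  if (inherits(hist, "angular_histogram")) {
    freq <- hist$aggregate
    centers <- hist$bin_centers
  } else {
    freq <- as.numeric(hist)
    centers <- (seq_along(freq) - 0.5) * 180 / length(freq)
  }
  if (sum(freq > 0) < 2L)
    stop("histogram needs at least 2 distinct nonzero bins")
  binw <- pi / length(freq)
  dens <- freq / sum(freq) / binw    # probability per radian over (0, pi]
  peaks <- .vm_peak_starts(dens, centers)

  obj <- function(p) {
    m <- vm_mixture(w = p[2], alpha1 = p[3] %% 180, a1 = p[4],
                    alpha2 = p[5] %% 180, a2 = p[6], b = p[1], order = FALSE)
    sum((vm_density(centers, m) - dens)^2)
  }
  lower <- c(0, 0, -360, 0, -360, 0)
  upper <- c(1, 1, 720, 100, 720, 100)
  starts <- list(
    c(0, 0.5, peaks[1], 1, peaks[2], 1),
    c(0, 0.5, peaks[2], 1, peaks[1], 1),
    c(0, 0.5, peaks[1], 3, peaks[2], 3),
    c(0.05, 0.5, peaks[1], 0.5, peaks[2], 0.5))
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("mixture fit failed from all starts")
  p <- best$par
  params <- vm_mixture(w = p[2], alpha1 = p[3] %% 180, a1 = p[4],
                       alpha2 = p[5] %% 180, a2 = p[6], b = p[1])
  dalpha <- abs(params$alpha1 - params$alpha2)
  dalpha <- min(dalpha, 180 - dalpha)
  degenerate <- params$w < 0.02 || params$w > 0.98 || dalpha < 3 ||
    params$a1 >= 99.5 || params$a2 >= 99.5
  structure(list(params = params, rss = best$value, converged = conv,
                 degenerate = degenerate,
                 fitted = vm_density(centers, params),
                 bin_centers = centers, density = dens),
            class = "vm_fit")
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("vm_fit (RSS %.3e%s%s):\n  ", x$rss,
              if (x$converged) "" else ", not converged",
              if (x$degenerate) ", degenerate second family" else ""))
  print(x$params)
  invisible(x)
}

#' @export
coef.vm_fit <- function(object, ...) {
  p <- object$params
  c(b = p$b, w = p$w, alpha1 = p$alpha1, a1 = p$a1,
    alpha2 = p$alpha2, a2 = p$a2)
}

#' @rdname vm_fit
#' @param object A `vm_fit`.
#' @param newdata Angles (degrees) at which to evaluate the fitted density;
#'   defaults to the fit's bin centers.
#' @param ... Unused.
#' @export
predict.vm_fit <- function(object, newdata = object$bin_centers, ...) {
  vm_density(newdata, object$params)
}

#' @rdname vm_fit
#' @param nsim Number of angles to draw from the fitted mixture (with the
#'   offset `b` dropped and weights renormalized implicitly by `b = 0`).
#' @param seed Optional seed.
#' @export
simulate.vm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$params
  vm_sample(vm_mixture(w = p$w, alpha1 = p$alpha1, a1 = p$a1,
                       alpha2 = p$alpha2, a2 = p$a2, b = 0),
            n = nsim, seed = seed)
}
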