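# Independent oracle implementations used to cross-check the package's
# vectorized / compiled routines. Deliberately literal and loop-based.

# Term-by-term evaluation of the axial center-of-mass equations:
# b_j = sqrt(1/tan^2(beta_j) + 1/tan^2(gamma_j)) = |tan(phi_j)|,
# C = (1/n) sum b_j/sqrt(1+b_j^2) cos(2 theta_j), S likewise with sin,
# Z = (1/n) sum SI_j / sqrt(1+b_j^2), SI = -(phi-90)/|phi-90| (1 at 90).
oracle_directional_summary <- function(theta_deg, phi_deg) {
  n <- length(theta_deg)
  C <- S <- Z <- 0
  for (j in seq_len(n)) {
    th <- theta_deg[j] * pi / 180
    ph <- phi_deg[j]
    if (ph == 90) {
      b <- Inf
      si <- 1
    } else {
      b <- abs(tan(ph * pi / 180))
      si <- -(ph - 90) / abs(ph - 90)
    }
    fac <- if (is.infinite(b)) 1 else b / sqrt(1 + b^2)
    zfac <- if (is.infinite(b)) 0 else 1 / sqrt(1 + b^2)
    C <- C + fac * cos(2 * th) / n
    S <- S + fac * sin(2 * th) / n
    Z <- Z + si * zfac / n
  }
  list(c_bar = C, s_bar = S, z_bar = Z, oi3d = sqrt(C^2 + S^2 + Z^2))
}

# Literal four-loop distance correlation (V-statistic): double-centered
# distance matrices computed element by element.
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
      B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
    }
  }
  dcov2 <- 0
  dvx <- 0
  dvy <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dcov2 <- dcov2 + A[i, j] * B[i, j] / n^2
      dvx <- dvx + A[i, j]^2 / n^2
      dvy <- dvy + B[i, j]^2 / n^2
    }
  }
  if (dvx == 0 || dvy == 0) return(0)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# Textbook one-way ANOVA F from the between/within sum-of-squares ratio.
oracle_anova_F <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Small in-plane fiber field built directly (no estimation): all phi = 90.
make_field <- function(theta, shape = NULL) {
  if (is.null(shape)) shape <- c(length(theta), 1, 1)
  list(theta = array(theta, shape),
       phi = array(90, shape),
       valid = array(TRUE, shape))
}

# As make_field but with explicit polar angles.
make_field_phi <- function(theta, phi) {
  shape <- c(length(theta), 1, 1)
  list(theta = array(theta, shape),
       phi = array(phi, shape),
       valid = array(TRUE, shape))
}

# Cached phantom + orientation estimate shared across test files (the
# estimation step is the expensive part of the suite).
.phantom_cache <- new.env(parent = emptyenv())
cached_single_family_phantom <- function() {
  if (is.null(.phantom_cache$single)) {
    spec <- fiber_phantom_spec(
      shape = c(24L, 96L, 96L),
      theta_mixture = vm_mixture(w = 1, alpha1 = 45, a1 = 50,
                                 alpha2 = 135, a2 = 1, order = FALSE),
      target_fill = 0.3, seed = 11)
    ph <- gen_fiber_stack(spec)
    ph$field <- estimate_orientation(ph$stack)
    .phantom_cache$single <- ph
  }
  .phantom_cache$single
}
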