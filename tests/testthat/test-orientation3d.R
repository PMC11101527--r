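test_that("polar angle from projections matches closed forms", {
  expect_equal(polar_from_projections(90, 90), 0)
  expect_equal(polar_from_projections(45, 90), 45)
  expect_equal(polar_from_projections(45, 45), atan(sqrt(2)) * 180 / pi)
  # in-plane limits: either projection flat
  expect_equal(polar_from_projections(0, 37), 90)
  expect_equal(polar_from_projections(112, 0), 90)
  # vectorized
  expect_equal(polar_from_projections(c(90, 45), c(90, 90)), c(0, 45))
  expect_error(polar_from_projections(180, 10))
  expect_error(polar_from_projections(-1, 10))
})

test_that("directional summary reproduces hand-computed identities", {
  s <- directional_summary(make_field(rep(30, 1000)))
  expect_equal(s$c_bar, 0.5)
  expect_equal(s$s_bar, sqrt(3) / 2)
  expect_equal(s$z_bar, 0)
  expect_equal(s$oi3d, 1)
  expect_equal(s$main_theta, 30)

  # all along z: C = S = 0, Z = 1
  fz <- list(theta = array(0, c(5, 1, 1)), phi = array(0, c(5, 1, 1)),
             valid = array(TRUE, c(5, 1, 1)))
  sz <- directional_summary(fz)
  expect_equal(sz$c_bar, 0)
  expect_equal(sz$s_bar, 0)
  expect_equal(sz$z_bar, 1)
  expect_equal(sz$oi3d, 1)

  # perpendicular in-plane pair cancels
  sp <- directional_summary(make_field(c(0, 90)))
  expect_equal(sp$oi3d, 0, tolerance = 1e-12)

  expect_error(directional_summary(make_field(numeric(0))), "valid")
})

test_that("directional summary agrees with the literal equation oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:100, 1)
    th <- runif(n, 0, 180)
    ph <- runif(n, 0.5, 179.5)
    ph[sample(n, 2)] <- 90  # exercise the in-plane special case
    f <- list(theta = array(th, c(n, 1, 1)), phi = array(ph, c(n, 1, 1)),
              valid = array(TRUE, c(n, 1, 1)))
    s <- directional_summary(f)
    o <- oracle_directional_summary(th, ph)
    expect_equal(s$c_bar, o$c_bar, tolerance = 1e-12)
    expect_equal(s$s_bar, o$s_bar, tolerance = 1e-12)
    expect_equal(s$z_bar, o$z_bar, tolerance = 1e-12)
    expect_equal(s$oi3d, o$oi3d, tolerance = 1e-12)
  }
})

test_that("directional summary is invariant to ordering and duplication", {
  set.seed(9)
  th <- runif(50, 0, 180)
  ph <- runif(50, 10, 170)
  s1 <- directional_summary(make_field_phi(th, ph))
  # ordering invariance: permute the (theta, phi) pairs together
  idx <- sample(50)
  s2 <- directional_summary(make_field_phi(th[idx], ph[idx]))
  s3 <- directional_summary(make_field_phi(rep(th, 2), rep(ph, 2)))
  for (fld in c("c_bar", "s_bar", "z_bar", "oi3d")) {
    expect_equal(s1[[fld]], s2[[fld]], tolerance = 1e-12)
    expect_equal(s1[[fld]], s3[[fld]], tolerance = 1e-12)
  }
})

test_that("rotating all theta by delta rotates main_theta, oi3d unchanged", {
  set.seed(10)
  th <- runif(200, 0, 180)
  base <- directional_summary(make_field(th))
  for (delta in c(10, 45, 90, 137)) {
    rot <- directional_summary(make_field((th + delta) %% 180))
    expect_equal(rot$oi3d, base$oi3d, tolerance = 1e-10)
    expect_equal(rot$main_theta %% 180, (base$main_theta + delta) %% 180,
                 tolerance = 1e-6)
  }
})

test_that("fold_angle reflects angles above 90 degrees", {
  expect_equal(fold_angle(135), 45)
  expect_equal(fold_angle(90), 90)
  expect_equal(fold_angle(27), 27)
  expect_equal(fold_angle(c(0, 90.5, 179)), c(0, 89.5, 1))
  expect_error(fold_angle(180), "\\[0, 180\\)")
  expect_error(fold_angle(-3), "\\[0, 180\\)")
})

test_that("layer histograms are normalized per layer with delta and uniform limits", {
  # delta distribution: all theta = 45
  f <- list(theta = array(45, c(3, 4, 4)), phi = array(90, c(3, 4, 4)),
            valid = array(TRUE, c(3, 4, 4)))
  h <- layer_histograms(f)
  expect_equal(rowSums(h$per_layer), rep(1, 3))
  expect_equal(h$per_layer[, 45], rep(1, 3))
  expect_equal(sum(h$aggregate), 1)
  expect_equal(h$aggregate[45], 1)

  # a layer with no valid voxels yields a zero row and is flagged
  f$valid[2, , ] <- FALSE
  h2 <- layer_histograms(f)
  expect_equal(h2$empty_layers, 2L)
  expect_equal(sum(h2$per_layer[2, ]), 0)

  # uniform angles approach 1/180 per bin
  set.seed(5)
  n <- 200000
  fu <- list(theta = array(runif(n, 0, 180), c(1, 1, n)),
             phi = array(90, c(1, 1, n)),
             valid = array(TRUE, c(1, 1, n)))
  hu <- layer_histograms(fu)
  expect_lt(max(abs(hu$aggregate - 1 / 180)), 0.0015)
})

test_that("orientation estimation recovers a single straight tube at 45 degrees", {
  # rasterize one in-plane cylinder at theta = 45 through the volume center
  d <- c(15L, 48L, 48L)
  vol <- array(0, d)
  for (t in seq(-34, 34, by = 0.5)) {
    cx <- round(24 + t * cos(pi / 4))
    cy <- round(24 + t * sin(pi / 4))
    if (cx < 2 || cx > 47 || cy < 2 || cy > 47) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz^2 + dy^2 + dx^2 > 2) next
      vol[8 + dz, cy + dy, cx + dx] <- 200
    }
  }
  st <- image_stack(vol)
  fld <- estimate_orientation(st)
  expect_gt(sum(fld$valid), 50)
  th <- fld$theta[fld$valid]
  # circular deviation from 45 (axial)
  dev <- abs(((th - 45 + 90) %% 180) - 90)
  expect_lt(median(dev), 3)
  expect_gt(median(fld$phi[fld$valid]), 80)
  expect_lt(median(fld$phi[fld$valid]), 100)
})

test_that("parallel tubes along the stretch axis give theta near 0 and phi near 90", {
  spec <- fiber_phantom_spec(
    shape = c(20L, 64L, 64L),
    theta_mixture = vm_mixture(w = 1, alpha1 = 0, a1 = 80, alpha2 = 90,
                               a2 = 1, order = FALSE),
    phi_concentration = 80, target_fill = 0.25, noise_sd = 2, seed = 21)
  ph <- gen_fiber_stack(spec)
  s <- directional_summary(estimate_orientation(ph$stack))
  dev0 <- min(s$main_theta, 180 - s$main_theta)
  expect_lt(dev0, 3)
  expect_lt(abs(s$main_phi - 90), 5)
})

test_that("uniform noise yields a near-zero orientation index", {
  set.seed(3)
  vol <- array(runif(32 * 64 * 64), c(32, 64, 64))
  fld <- estimate_orientation(image_stack(vol))
  s <- directional_summary(fld)
  expect_gt(s$n_valid, 1e4)
  expect_lt(s$oi3d, 0.05)
})

test_that("in-plane 90-degree stack rotation shifts the theta histogram by 90", {
  ph <- cached_single_family_phantom()
  h <- layer_histograms(ph$field)
  # rotate the volume 90 degrees in-plane: (y, x) -> (x, ny + 1 - y)
  vox <- ph$stack$voxels
  d <- dim(vox)
  rot <- array(0, c(d[1], d[3], d[2]))
  for (z in seq_len(d[1])) rot[z, , ] <- t(vox[z, , ])[, d[2]:1]
  hrot <- layer_histograms(estimate_orientation(image_stack(rot)))
  # aggregate shifted by 90 bins should match the original closely
  shifted <- c(hrot$aggregate[91:180], hrot$aggregate[1:90])
  # compare smoothed profiles (rasterization details differ voxel by voxel)
  smooth <- function(v) stats::filter(c(v, v, v), rep(1 / 9, 9))[181:360]
  expect_gt(cor(smooth(h$aggregate), smooth(shifted)), 0.95)
  # and the main angle rotates by 90
  s <- directional_summary(ph$field)
  srot <- directional_summary(estimate_orientation(image_stack(rot)))
  expect_lt(abs(((srot$main_theta - s$main_theta) %% 180) - 90), 5)
})

test_that("degenerate inputs are refused or flagged", {
  expect_error(estimate_orientation(image_stack(array(1, c(5, 5, 5))),
                                    window_size = 11), "window_size")
  expect_warning(fld <- estimate_orientation(
    image_stack(array(0, c(12, 12, 12)))), "no voxels")
  expect_equal(sum(fld$valid), 0)
})
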