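test_that("spatially uniform dA/dt induces no current (E ~ 0)", {
  ph <- make_torso_phantom(body_params(resolution = 4))
  d <- dim(ph$labels)
  da <- make_grid_field(array(1, d), array(0.5, d), array(-0.25, d))
  phi <- solve_scalar_potential(ph, da)
  E <- compute_E(phi, da, ph)
  expect_lt(max(E$magnitude), 1e-5 * 1)
})

test_that("circular cylinder solve matches E_phi = 50 r at interior points", {
  fx <- fx_circular_solve(2)
  E <- fx$E
  ax <- gradstim:::grid_axes(fx$model)
  iz <- dim(E$magnitude)[3] %/% 2
  for (r in c(0.05, 0.1, 0.15)) {
    ix <- which.min(abs(ax$x - r))
    iy <- which.min(abs(ax$y))
    expect_lt(abs(E$magnitude[ix, iy, iz] / (50 * ax$x[ix]) - 1), 0.02)
  }
  # E is zero outside the conductor and magnitude is the vector norm
  expect_true(all(E$magnitude[fx$model$labels == 0L] == 0))
  expect_equal(E$magnitude,
               sqrt(E$vectors$x^2 + E$vectors$y^2 + E$vectors$z^2))
})

test_that("elliptical cylinder solve matches the closed-form field", {
  a <- 0.2; b <- 0.125
  ell <- make_homogeneous_cylinder(a, b, 0.012, sigma = 0.2,
                                   resolution = 4, myocardium = "interior")
  src <- make_ideal_field("uniform_B", 1)
  da <- dAdt_grid(src, ell, drive_spec(100))
  phi <- solve_scalar_potential(ell, da)
  E <- compute_E(phi, da, ell)
  an <- analytic_ellipse_E(ell, a, b)
  reg <- ell$masks$myocardium
  # max |E| over the margin region vs closed form over the same region
  expect_lt(abs(max(E$magnitude[reg]) / max(an$mag[reg]) - 1), 0.05)
  # componentwise agreement at the 90th percentile of |error|
  err <- abs(E$vectors$x[reg] - an$Ex[reg]) +
    abs(E$vectors$y[reg] - an$Ey[reg])
  expect_lt(unname(quantile(err, 0.9)) / max(an$mag[reg]), 0.03)
})

test_that("solutions superpose and scale linearly", {
  fx <- fx_circular_solve(2)
  cyl <- fx$model
  d <- dim(cyl$labels)
  v1 <- fx$dAdt$values
  ax <- gradstim:::grid_axes(cyl)
  X <- array(rep(ax$x, times = prod(d[2:3])), d)
  Z <- array(rep(ax$z, each = d[1] * d[2]), d)
  # independent second excitation: ideal z-gradient drive
  ug <- make_ideal_field("uniform_gradient", 1)
  v2 <- dAdt_grid(ug, cyl, drive_spec(100, axes = "z"))$values
  sum_field <- make_grid_field(v1[[1]] + v2[[1]], v1[[2]] + v2[[2]],
                               v1[[3]] + v2[[3]])
  E1 <- fx$E
  phi2 <- solve_scalar_potential(cyl, make_grid_field(v2[[1]], v2[[2]],
                                                      v2[[3]]))
  E2 <- compute_E(phi2, make_grid_field(v2[[1]], v2[[2]], v2[[3]]), cyl)
  phis <- solve_scalar_potential(cyl, sum_field)
  Es <- compute_E(phis, sum_field, cyl)
  scale <- max(Es$magnitude)
  expect_lt(max(abs(Es$vectors$x - E1$vectors$x - E2$vectors$x)) / scale,
            1e-5)
  expect_lt(max(abs(Es$vectors$y - E1$vectors$y - E2$vectors$y)) / scale,
            1e-5)
  # doubling the excitation doubles E exactly (floating-point scaling)
  dbl <- make_grid_field(2 * v1[[1]], 2 * v1[[2]], 2 * v1[[3]])
  phid <- solve_scalar_potential(cyl, dbl)
  Ed <- compute_E(phid, dbl, cyl)
  expect_lt(max(abs(Ed$magnitude - 2 * E1$magnitude)) /
              max(E1$magnitude), 1e-6)
})

test_that("zero potential reduces E to -dA/dt inside the conductor", {
  cyl <- make_homogeneous_cylinder(0.1, 0.1, 0.05, resolution = 8)
  d <- dim(cyl$labels)
  da <- make_grid_field(array(2, d), array(-1, d), array(0.5, d))
  phi0 <- structure(list(phi = array(0, d)), class = "potential_grid")
  E <- compute_E(phi0, da, cyl)
  cond <- cyl$labels > 0L
  # interior voxels carry -dA/dt exactly; boundary voxels blend with the
  # zero-normal-current face convention
  int <- erode_mask(cond)
  expect_equal(E$vectors$x[int], rep(-2, sum(int)))
  expect_equal(E$vectors$y[int], rep(1, sum(int)))
  expect_true(all(E$magnitude[!cond] == 0))
})

test_that("solver errors are informative", {
  cyl <- make_homogeneous_cylinder(0.1, 0.1, 0.05, resolution = 8)
  d <- dim(cyl$labels)
  ax <- gradstim:::grid_axes(cyl)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  da <- make_grid_field(-50 * Y, 50 * array(rep(ax$x, prod(d[2:3])), d),
                        array(0, d))
  expect_error(solve_scalar_potential(cyl, da,
                                      solve_config(max_iterations = 2)),
               "did not converge")
  bad <- make_grid_field(array(0, d + 1L), array(0, d + 1L),
                         array(0, d + 1L))
  expect_error(solve_scalar_potential(cyl, bad), "do not match")
  small <- make_torso_phantom(body_params(resolution = 5))
  expect_error(compute_E(structure(list(phi = array(0, c(2, 2, 2))),
                                   class = "potential_grid"),
                         da, small), "mismatch")
})

test_that("current conservation residual behaves as a diagnostic", {
  fx <- fx_circular_solve(2)
  # converged solve: residual at solver-tolerance level
  expect_lt(current_conservation_residual(fx$E, fx$model), 1e-6)
  # negative control: E = -dA/dt without the potential, heterogeneous sigma
  ph <- make_torso_phantom(body_params(resolution = 4))
  da <- dAdt_grid(fx_y_coil(), ph, drive_spec(axes = "y"))
  phi0 <- structure(list(phi = array(0, dim(ph$labels))),
                    class = "potential_grid")
  E0 <- compute_E(phi0, da, ph)
  E0$phi <- NULL
  expect_gt(current_conservation_residual(E0, ph), 0.01)
})

test_that("analytic solenoidal fields give convergent residuals", {
  res_err <- sapply(c(8, 4), function(res) {
    cyl <- make_homogeneous_cylinder(0.2, 0.2, 0.05, sigma = 0.2,
                                     resolution = res)
    d <- dim(cyl$labels)
    ax <- gradstim:::grid_axes(cyl)
    X <- array(rep(ax$x, times = prod(d[2:3])), d)
    Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
    cond <- array(cyl$labels > 0L, d)
    # divergence-free stream-function field psi = sin(20x) sin(20y)
    vx <- 20 * sin(20 * X) * cos(20 * Y) * cond
    vy <- -20 * cos(20 * X) * sin(20 * Y) * cond
    Em <- structure(list(vectors = list(x = vx, y = vy, z = array(0, d)),
                         magnitude = sqrt(vx^2 + vy^2), phi = NULL,
                         dAdt = NULL),
                    class = "efield_map")
    current_conservation_residual(Em, cyl)
  })
  expect_lt(res_err[2], res_err[1])
  expect_lt(res_err[2], 0.05)
})

test_that("staircasing produces |E| jumps at myocardium-lung interfaces", {
  fx <- fx_torso_solve(2)
  lab <- fx$model$labels
  jumps <- c()
  for (ax in 1:3) {
    up <- gradstim:::shift_arr(lab, ax, -1)
    Eu <- gradstim:::shift_arr(fx$E$magnitude, ax, -1)
    sel <- lab == 3L & up == 2L
    jumps <- c(jumps, abs(fx$E$magnitude[sel] - Eu[sel]) /
                 pmax(fx$E$magnitude[sel], Eu[sel]))
  }
  expect_gt(length(jumps), 0)
  expect_gt(max(jumps), 0.10)
})

test_that("disconnected conductor components are handled independently", {
  d <- c(12, 8, 8)
  lab <- array(0L, d)
  lab[2:5, 3:6, 3:6] <- 1L
  lab[8:11, 3:6, 3:6] <- 1L
  tt <- tissue_table(c(0L, 1L), c("air", "tissue"), c(0, 0.3))
  m <- voxel_model(lab, 5, c(0, 0, 0), tt)
  da <- make_grid_field(array(1, d), array(0, d), array(0, d))
  phi <- solve_scalar_potential(m, da)
  for (blk in list(2:5, 8:11)) {
    vals <- phi$phi[blk, 3:6, 3:6]
    expect_lt(abs(mean(vals)), 1e-10)
  }
  E <- compute_E(phi, da, m)
  expect_lt(max(E$magnitude), 1e-6)
})
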