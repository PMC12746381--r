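# Shared fixtures, memoized so expensive solves run once per suite.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# circular cylinder r = 0.2 m under uniform dB/dt = 100 T/s, solved
fx_circular_solve <- function(res = 2) {
  fixture(paste0("circ", res), function() {
    src <- make_ideal_field("uniform_B", 1)
    drv <- drive_spec(slew = 100)
    cyl <- make_homogeneous_cylinder(0.2, 0.2, 0.01, sigma = 0.2,
                                     resolution = res, myocardium = "all")
    da <- dAdt_grid(src, cyl, drv)
    phi <- solve_scalar_potential(cyl, da)
    list(model = cyl, dAdt = da, phi = phi,
         E = compute_E(phi, da, cyl))
  })
}

# heterogeneous torso solved with a Golay Y coil, heart near the coil eye
fx_torso_solve <- function(res = 2) {
  fixture(paste0("torso", res), function() {
    coil <- fx_y_coil()
    ph <- gradstim:::shift_model_z(
      make_torso_phantom(body_params(resolution = res)), 0.20)
    da <- dAdt_grid(coil, ph, drive_spec(axes = "y"))
    phi <- solve_scalar_potential(ph, da)
    list(model = ph, dAdt = da, phi = phi,
         E = compute_E(phi, da, ph))
  })
}

fx_y_coil <- function() {
  fixture("ycoil", function() make_axis_coil("y", 0.70, 1.40))
}

fx_population <- function() {
  fixture("pop", function() make_population(2, seed = 3, resolution = 6))
}

# small seeded study reused by sweep/aggregation tests
fx_study <- function() {
  fixture("study", function() {
    cfg <- sweep_config(landmark_step = 0.05, n_landmarks = 3, axes = "y",
                        slew = 100)
    run_study(fx_population(), list(gradient_set(0.70, 1.40, name = "GC1")),
              cfg, seed = 3)
  })
}

# analytic in-plane E field of an elliptical cylinder under uniform dB/dt
analytic_ellipse_E <- function(model, a, b, dBdt = 100) {
  ax <- gradstim:::grid_axes(model)
  d <- dim(model$labels)
  X <- array(rep(ax$x, times = prod(d[2:3])), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  al <- dBdt * a^2 / (a^2 + b^2)
  be <- dBdt * b^2 / (a^2 + b^2)
  list(X = X, Y = Y, Ex = al * Y, Ey = -be * X,
       mag = sqrt((al * Y)^2 + (be * X)^2))
}

# brute-force 6-neighbor erosion oracle (explicit loop, small masks only)
brute_erode <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else FALSE,
      if (i < d[1]) mask[i + 1, j, k] else FALSE,
      if (j > 1) mask[i, j - 1, k] else FALSE,
      if (j < d[2]) mask[i, j + 1, k] else FALSE,
      if (k > 1) mask[i, j, k - 1] else FALSE,
      if (k < d[3]) mask[i, j, k + 1] else FALSE)
    if (!all(nb)) out[i, j, k] <- FALSE
  }
  out
}

make_grid_field <- function(vx, vy, vz) {
  structure(list(values = list(vx, vy, vz), dims = dim(vx)),
            class = "grid_field")
}
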