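mu0 <- 4e-7 * pi

test_that("single-loop field matches the loop-center closed form", {
  lp <- gradstim:::circle_loop(0.3, 0, 1, 72)
  cl <- coil_model(list(lp), "z", 0.6, 1.2, override = TRUE)
  B <- biot_savart_B(cl, matrix(0, 1, 3))$values
  expect_lt(abs(B[3] / (mu0 / (2 * 0.3)) - 1), 1e-3)
  expect_equal(B[1], 0, tolerance = 1e-15)
  # on-axis point: closed form mu0 I R^2 / 2 (R^2 + z^2)^(3/2)
  Bz <- biot_savart_B(cl, matrix(c(0, 0, 0.2), 1))$values[3]
  expect_lt(abs(Bz / (mu0 * 0.3^2 / (2 * (0.3^2 + 0.2^2)^1.5)) - 1), 1e-3)
})

test_that("fields are linear in current and translation invariant", {
  mk <- function(cur, shift = c(0, 0, 0)) {
    lp <- gradstim:::circle_loop(0.3, 0, cur, 48)
    lp$vertices <- sweep(lp$vertices, 2, shift, "+")
    coil_model(list(lp), "z", 0.6, 1.2, override = TRUE)
  }
  pts <- rbind(c(0.05, 0.08, 0.1), c(-0.1, 0.02, -0.05))
  B1 <- biot_savart_B(mk(1), pts)$values
  B2 <- biot_savart_B(mk(2), pts)$values
  expect_equal(B2, 2 * B1)
  A1 <- vector_potential_A(mk(1), pts)$values
  Am <- vector_potential_A(mk(-1), pts)$values
  expect_equal(Am, -A1)
  sh <- c(0.07, -0.03, 0.12)
  A2 <- vector_potential_A(mk(1, sh), sweep(pts, 2, sh, "+"))$values
  expect_equal(A2, A1, tolerance = 1e-12)
})

test_that("opposed coaxial loops cancel B on the midplane axis", {
  loops <- list(gradstim:::circle_loop(0.3, 0.15, 1, 72),
                gradstim:::circle_loop(0.3, -0.15, -1, 72))
  cl <- coil_model(loops, "z", 0.6, 1.2, override = TRUE)
  B <- biot_savart_B(cl, matrix(0, 1, 3))$values
  expect_lt(max(abs(B)), 1e-18)
})

test_that("numerical curl of A equals B", {
  coil <- fx_y_coil()
  hh <- 1e-4
  for (pt in list(c(0.05, 0.02, 0.03), c(-0.1, 0.08, -0.12),
                  c(0.02, 0.15, 0.2))) {
    f <- function(q) vector_potential_A(coil, matrix(q, 1))$values
    dA <- function(i, j)
      (f(pt + hh * (1:3 == j))[i] - f(pt - hh * (1:3 == j))[i]) / (2 * hh)
    curl <- c(dA(3, 2) - dA(2, 3), dA(1, 3) - dA(3, 1), dA(2, 1) - dA(1, 2))
    B <- biot_savart_B(coil, matrix(pt, 1))$values
    expect_lt(max(abs(curl - B)) / max(abs(B)), 0.005)
  }
})

test_that("loop far field decays as 1/r^3", {
  lp <- gradstim:::circle_loop(0.3, 0, 1, 72)
  cl <- coil_model(list(lp), "z", 0.6, 1.2, override = TRUE)
  r <- c(3, 5.3, 9.5, 16.9, 30)
  Bn <- sqrt(rowSums(biot_savart_B(cl, cbind(0, 0, r))$values^2))
  slope <- diff(log(Bn)) / diff(log(r))
  expect_true(all(abs(slope + 3) < 0.05))
})

test_that("field points too close to a wire raise a singular error", {
  lp <- gradstim:::circle_loop(0.3, 0, 1, 8)
  cl <- coil_model(list(lp), "z", 0.6, 1.2, override = TRUE)
  expect_error(biot_savart_B(cl, matrix(c(0.3, 0, 0), 1)), "loop")
})

test_that("Maxwell pair gradient efficiency matches its closed form", {
  R <- 0.35
  d <- sqrt(3) / 2 * R
  g_cf <- 3 * mu0 * R^2 * d / (R^2 + d^2)^2.5
  mz <- make_axis_coil("z", 0.70, 1.40, shielded = FALSE)
  expect_lt(abs(gradient_efficiency(mz) / g_cf - 1), 1e-3)
  # turns scale the efficiency linearly
  mz3 <- make_axis_coil("z", 0.70, 1.40, shielded = FALSE, turns = 3)
  expect_equal(gradient_efficiency(mz3), 3 * gradient_efficiency(mz),
               tolerance = 1e-12)
})

test_that("axis coils produce their requested primary gradient", {
  step <- 1e-3
  for (ax in c("x", "y", "z")) {
    coil <- make_axis_coil(ax, 0.70, 1.40)
    dvec <- switch(ax, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
    pts <- rbind(dvec * step, -dvec * step)
    Bz <- biot_savart_B(coil, pts)$values[, 3]
    g_axis <- (Bz[1] - Bz[2]) / (2 * step)
    expect_equal(g_axis, gradient_efficiency(coil), tolerance = 1e-9)
    # the other two gradient components vanish at isocenter
    others <- setdiff(c("x", "y", "z"), ax)
    for (o in others) {
      ov <- switch(o, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
      Bzo <- biot_savart_B(coil, rbind(ov * step, -ov * step))$values[, 3]
      expect_lt(abs((Bzo[1] - Bzo[2]) / (2 * step)), 1e-3 * abs(g_axis))
    }
  }
})

test_that("the y coil is the x coil rotated 90 degrees about z", {
  cx <- make_axis_coil("x", 0.70, 1.40)
  cy <- make_axis_coil("y", 0.70, 1.40)
  rot <- function(v, ang) {
    Rm <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0,
                   0, 0, 1), 3, 3)
    v %*% t(Rm)
  }
  pts <- rbind(c(0.05, 0.1, 0.15), c(-0.12, 0.03, -0.3), c(0.2, 0, 0.1))
  By <- biot_savart_B(cy, pts)$values
  Bx <- biot_savart_B(cx, rot(pts, -pi / 2))$values
  expect_equal(By, rot(Bx, pi / 2), tolerance = 1e-10)
})

test_that("shield windings reduce the stray field at twice the radius", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ring <- cbind(0.70 * cos(th), 0.70 * sin(th), 0.15)
  for (ax in c("z", "x")) {
    cs <- make_axis_coil(ax, 0.70, 1.40, shielded = TRUE)
    cu <- make_axis_coil(ax, 0.70, 1.40, shielded = FALSE)
    ns <- sqrt(rowSums(biot_savart_B(cs, ring)$values^2))
    nu <- sqrt(rowSums(biot_savart_B(cu, ring)$values^2))
    expect_true(all(ns < nu))
  }
  expect_error(make_axis_coil("z", 0.70, 1.40, shield_scale = 0.9),
               "shield radius")
})

test_that("preset geometry ranges are enforced unless overridden", {
  expect_error(make_axis_coil("z", 0.50, 1.40), "inner diameter")
  expect_error(make_axis_coil("z", 0.70, 2.0), "length")
  expect_s3_class(make_axis_coil("z", 0.50, 2.0, override = TRUE),
                  "coil_model")
})

test_that("ideal field sources obey their construction", {
  ub <- make_ideal_field("uniform_B", 2.5)
  pts <- rbind(c(0.1, -0.2, 0.3), c(0, 0, 0))
  expect_equal(biot_savart_B(ub, pts)$values[, 3], c(2.5, 2.5))
  # curl A = (0, 0, B0) exactly
  hh <- 1e-5
  f <- function(q) vector_potential_A(ub, matrix(q, 1))$values
  p <- c(0.07, 0.03, -0.1)
  curl_z <- (f(p + c(hh, 0, 0))[2] - f(p - c(hh, 0, 0))[2] -
             f(p + c(0, hh, 0))[1] + f(p - c(0, hh, 0))[1]) / (2 * hh)
  expect_equal(curl_z, 2.5, tolerance = 1e-8)
  ug0 <- make_ideal_field("uniform_gradient", 0)
  expect_true(all(vector_potential_A(ug0, pts)$values == 0))
  ug <- make_ideal_field("uniform_gradient", 0.05)
  expect_equal(gradient_efficiency(ug), 0.05)
  expect_error(gradient_efficiency(ub), "degenerate")
})

test_that("compliance peak dB/dt follows the stated scaling", {
  ug <- make_ideal_field("uniform_gradient", 1)
  cv <- compliance_volume(z_extent = c(-0.5, 0.5))
  expect_equal(compliance_peak_dBdt(ug, drive_spec(100, axes = "z"), cv),
               50, tolerance = 1e-12)
  expect_equal(compliance_peak_dBdt(ug, drive_spec(200, axes = "z"), cv),
               100, tolerance = 1e-12)
  ub <- make_ideal_field("uniform_B", 1)
  for (zext in list(c(-0.5, 0.5), c(-0.1, 0.4)))
    expect_equal(compliance_peak_dBdt(
      ub, drive_spec(100), compliance_volume(z_extent = zext)), 100)
  # invariant to coil current amplitude
  c1 <- make_axis_coil("z", 0.70, 1.40, turns = 1)
  c3 <- make_axis_coil("z", 0.70, 1.40, turns = 3)
  expect_equal(compliance_peak_dBdt(c1, drive_spec(100, axes = "z")),
               compliance_peak_dBdt(c3, drive_spec(100, axes = "z")),
               tolerance = 1e-10)
  expect_error(compliance_volume(z_extent = c(0.5, -0.5)), "z_min")
})

test_that("coil JSON serialization round-trips", {
  coil <- make_axis_coil("z", 0.70, 1.40)
  f <- withr::local_tempfile(fileext = ".json")
  write_coil_model(coil, f)
  back <- read_coil_model(f)
  pts <- rbind(c(0.1, 0.05, 0.2), c(0, 0.15, -0.1))
  expect_equal(biot_savart_B(back, pts)$values,
               biot_savart_B(coil, pts)$values, tolerance = 1e-12)
})
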