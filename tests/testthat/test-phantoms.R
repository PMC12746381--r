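test_that("tissue table validates labels and conductivities", {
  tt <- default_tissue_table()
  expect_setequal(tt$name, c("air", "torso", "lung", "myocardium", "blood"))
  expect_equal(tt$sigma[tt$name == "myocardium"], 0.385)
  expect_equal(tt$sigma[tt$name == "lung"], 0.101)
  expect_equal(tt$sigma[tt$name == "blood"], 0.662)
  expect_error(tissue_table(c(1, 1), c("a", "b"), c(1, 2)), "unique")
  expect_error(tissue_table(0, "air", 0.5), "reserved")
  expect_error(tissue_table(1, "a", -1), ">= 0")
})

test_that("homogeneous cylinder voxelization matches analytic volume", {
  cyl <- make_homogeneous_cylinder(0.2, 0.2, 0.6, resolution = 5)
  vol <- pi * 0.2^2 * 0.6
  expect_lt(abs(sum(cyl$labels == 1L) * 0.005^3 / vol - 1), 0.02)

  ell <- make_homogeneous_cylinder(0.2, 0.125, 0.1, resolution = 4)
  ax <- gradstim:::grid_axes(ell)
  d <- dim(ell$labels)
  X <- array(rep(ax$x, times = prod(d[2:3])), d)
  Y <- array(rep(rep(ax$y, each = d[1]), times = d[3]), d)
  outside <- (X / 0.2)^2 + (Y / 0.125)^2 > 1
  expect_true(all(ell$labels[outside] == 0L))
})

test_that("cylinder voxel volume error shrinks with resolution", {
  vol <- pi * 0.2 * 0.125 * 0.1
  err <- sapply(c(5, 1), function(res) {
    m <- make_homogeneous_cylinder(0.2, 0.125, 0.1, resolution = res)
    abs(sum(m$labels == 1L) * (res / 1000)^3 / vol - 1)
  })
  expect_lt(err[2], err[1])
})

test_that("degenerate cylinder geometry is rejected", {
  expect_error(make_homogeneous_cylinder(0.03, 0.03, 0.1, resolution = 5),
               "degenerate")
  expect_error(make_homogeneous_cylinder(0.2, 0.03, 0.1, resolution = 5),
               "degenerate")
  # sigma = 0 still builds a (vacuous) model; the solver refuses it
  m0 <- make_homogeneous_cylinder(0.2, 0.2, 0.1, sigma = 0, resolution = 8)
  expect_error(fd_system(m0), "no conducting voxel")
})

test_that("torso phantom geometry is labeled with innermost precedence", {
  ph <- make_torso_phantom(body_params(resolution = 2))
  lab <- ph$labels
  expect_setequal(sort(unique(as.vector(lab))), 0:4)
  # masks congruent and consistent with labels
  expect_true(all(ph$masks$myocardium == (lab == 3L)))
  expect_true(all(ph$masks$heart_total == (lab == 3L | lab == 4L)))
  # myocardium-lung interfaces exist (staircasing substrate)
  adj <- 0
  for (ax in 1:3) {
    up <- gradstim:::shift_arr(lab, ax, -1)
    adj <- adj + sum(lab == 3L & up == 2L)
  }
  expect_gt(adj, 0)
})

test_that("myocardium voxel count matches the analytic shell volume", {
  p <- body_params(resolution = 1)
  ph <- make_torso_phantom(p)
  g <- gradstim:::resolve_body_params(p)
  shell <- 4 / 3 * pi * (prod(g$heart) - prod(g$blood))
  expect_lt(abs(sum(ph$masks$myocardium) / (shell / 1e-9) - 1), 0.10)
})

test_that("heart_scale scales myocardial volume with its cube", {
  base <- body_params(heart_semiaxes = c(0.030, 0.026, 0.032),
                      wall_thickness = 0.006, resolution = 1)
  big <- body_params(heart_semiaxes = c(0.030, 0.026, 0.032),
                     wall_thickness = 0.006, heart_scale = 1.22,
                     resolution = 1)
  v0 <- sum(make_torso_phantom(base)$masks$myocardium)
  v1 <- sum(make_torso_phantom(big)$masks$myocardium)
  expect_lt(abs(v1 / v0 / 1.22^3 - 1), 0.02)
})

test_that("torso phantom generation is deterministic", {
  p <- body_params(resolution = 3)
  m1 <- make_torso_phantom(p)
  m2 <- make_torso_phantom(p)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$masks, m2$masks)
})

test_that("conflicting and escaping geometries are rejected", {
  expect_error(body_params(lung_center_x = c(-0.045, 0.045)),
               "blood pool")
  expect_error(body_params(heart_center = c(-0.06, 0.005, 0)),
               "inside the torso")
  expect_error(body_params(wall_thickness = 0.05), "wall thickness")
  expect_error(body_params(torso_a = -0.1), "positive")
})

test_that("population generation is seeded and honors ranges", {
  pop1 <- make_population(3, seed = 7, resolution = 6)
  pop2 <- make_population(3, seed = 7, resolution = 6)
  expect_identical(lapply(pop1, `[[`, "labels"),
                   lapply(pop2, `[[`, "labels"))
  heights <- sapply(pop1, function(m) m$anthropometry$height)
  expect_true(all(heights >= 1.53 & heights <= 1.90))
  # torso z extent ~ 0.30 x height
  for (m in pop1) {
    d <- dim(m$labels)
    zlen <- sum(apply(m$labels > 0, 3, any)) * m$spacing / 1000
    expect_lt(abs(zlen - 0.30 * m$anthropometry$height), 0.02)
  }
})

test_that("degenerate point ranges reproduce the explicit phantom", {
  pop <- make_population(1, seed = 1,
                         ranges = list(height = c(1.70, 1.70),
                                       weight = c(80, 80)),
                         resolution = 6)
  direct <- make_torso_phantom(
    body_params_from_anthropometry(1.70, 80, resolution = 6))
  expect_identical(pop[[1]]$labels, direct$labels)
})

test_that("infeasible population ranges fail before generation", {
  expect_error(make_population(2, seed = 1,
                               ranges = list(heart_scale = c(4, 4)),
                               resolution = 6))
  expect_error(make_population(2, seed = 1,
                               ranges = list(height = c(1.9, 1.5))),
               "invalid range")
})

test_that("voxel model invariants are enforced", {
  lab <- array(0L, c(4, 4, 4))
  tt <- default_tissue_table()
  expect_error(voxel_model(lab, 20, c(0, 0, 0), tt), "spacing")
  lab[2, 2, 2] <- 9L
  expect_error(voxel_model(lab, 2, c(0, 0, 0), tt), "missing from")
  lab[2, 2, 2] <- 3L
  bad_mask <- array(FALSE, c(4, 4, 4))
  expect_error(voxel_model(lab, 2, c(0, 0, 0), tt,
                           masks = list(myocardium = bad_mask)), "empty")
  bad_mask[1, 1, 1] <- TRUE
  expect_error(voxel_model(lab, 2, c(0, 0, 0), tt,
                           masks = list(myocardium = bad_mask)),
               "myocardium label")
})

test_that("voxel model text serialization round-trips", {
  ph <- make_torso_phantom(body_params(resolution = 4))
  dir <- withr::local_tempdir()
  write_voxel_model(ph, dir)
  back <- read_voxel_model(dir)
  expect_identical(back$labels, ph$labels)
  expect_identical(back$masks, ph$masks)
  expect_equal(back$origin, ph$origin)
  expect_equal(back$tissues$sigma, ph$tissues$sigma)
})
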