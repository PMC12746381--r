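# Synthetic voxel body models.
#
# Geometry primitives are elliptical cylinders (torso) and ellipsoids (heart,
# blood pool, lungs). Voxels are assigned by center-point membership with a
# fixed innermost-wins precedence (blood > myocardium > lung > torso bulk),
# which deliberately produces hexahedral staircasing at conductivity
# interfaces -- the artifact the percentile metrics are designed to mitigate.

#' Tissue conductivity table
#'
#' Builds the lookup table mapping integer voxel labels to tissue names and
#' low-frequency electrical conductivities. Label 0 is reserved for
#' background air (sigma = 0).
#'
#' @param label integer vector of unique non-negative labels.
#' @param name character vector of tissue names.
#' @param sigma numeric vector of conductivities in S/m (>= 0).
#' @return A `data.frame` with columns `label`, `name`, `sigma` and class
#'   `tissue_table`.
#' @examples
#' default_tissue_table()
#' @export
tissue_table <- function(label, name, sigma) {
  stopifnot(length(label) == length(name), length(label) == length(sigma))
  label <- as.integer(label)
  if (anyDuplicated(label)) stop("tissue labels must be unique")
  if (any(label < 0)) stop("tissue labels must be non-negative")
  if (any(sigma < 0)) stop("conductivities must be >= 0")
  if (any(label == 0 & sigma != 0))
    stop("label 0 is reserved for background air with sigma = 0")
  tab <- data.frame(label = label, name = as.character(name),
                    sigma = as.numeric(sigma), stringsAsFactors = FALSE)
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Default five-class tissue table
#'
#' Conductivities for the three tissues that drive staircasing at cardiac
#' interfaces (myocardium 0.385 S/m, lung 0.101 S/m, blood 0.662 S/m, from
#' the IT'IS low-frequency database values used in gradient-coil dosimetry),
#' plus a bulk torso tissue whose conductivity is a documented free choice.
#'
#' @param torso_sigma conductivity of the averaged torso bulk tissue in S/m.
#' @return a [tissue_table()].
#' @export
default_tissue_table <- function(torso_sigma = 0.23) {
  tissue_table(label = c(0L, 1L, 2L, 3L, 4L),
               name = c("air", "torso", "lung", "myocardium", "blood"),
               sigma = c(0, torso_sigma, 0.101, 0.385, 0.662))
}

#' Voxel body model
#'
#' Container for a labeled 3-D conductivity grid in isocenter coordinates.
#' The grid is uniform and isotropic; `origin` is the position (m) of the
#' outer corner of voxel `[1, 1, 1]`, with z along the bore axis.
#'
#' @param labels integer 3-D array of tissue labels.
#' @param spacing isotropic voxel edge length in mm, in (0.1, 10).
#' @param origin numeric length-3, corner of voxel `[1,1,1]` in m.
#' @param tissues a [tissue_table()] covering every label present.
#' @param masks named list of logical arrays congruent with `labels`;
#'   a `"myocardium"` mask must be non-empty and, when a tissue named
#'   `"myocardium"` exists, lie entirely on myocardium-labeled voxels.
#' @param name identifier used in ratio tables.
#' @return object of class `voxel_model`.
#' @export
voxel_model <- function(labels, spacing, origin, tissues, masks = list(),
                        name = "model") {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)[1]
  if (!(spacing > 0.1 && spacing < 10))
    stop("voxel spacing must lie in (0.1, 10) mm")
  present <- sort(unique(as.vector(labels)))
  if (!all(present %in% tissues$label))
    stop("labels present in the grid are missing from the tissue table: ",
         paste(setdiff(present, tissues$label), collapse = ", "))
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dim(labels)))
      stop("mask '", nm, "' dimensions differ from label grid")
  }
  if (!is.null(masks$myocardium)) {
    if (!any(masks$myocardium)) stop("myocardium mask is empty")
    myo_lab <- tissues$label[tissues$name == "myocardium"]
    if (length(myo_lab) == 1 &&
        any(masks$myocardium & labels != myo_lab))
      stop("myocardium mask voxels must carry the myocardium label")
  }
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), tissues = tissues,
                 masks = masks, name = name),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat("voxel_model '", x$name, "': ", d[1], "x", d[2], "x", d[3],
      " @ ", x$spacing, " mm\n", sep = "")
  cat("  conducting voxels:", sum(x$labels > 0L), "\n")
  for (nm in names(x$masks))
    cat("  mask ", nm, ": ", sum(x$masks[[nm]]), " voxels\n", sep = "")
  invisible(x)
}

# voxel-center coordinate vectors (m) along each axis
grid_axes <- function(model) {
  d <- dim(model$labels)
  h <- model$spacing / 1000
  list(x = model$origin[1] + (seq_len(d[1]) - 0.5) * h,
       y = model$origin[2] + (seq_len(d[2]) - 0.5) * h,
       z = model$origin[3] + (seq_len(d[3]) - 0.5) * h,
       h = h)
}

# n x 3 matrix of voxel-center positions for voxels selected by `idx`
# (linear indices); all voxels if NULL
voxel_centers <- function(model, idx = NULL) {
  ax <- grid_axes(model)
  d <- dim(model$labels)
  if (is.null(idx)) idx <- seq_len(prod(d))
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  cbind(ax$x[i], ax$y[j], ax$z[k])
}

sigma_grid <- function(model) {
  lut <- numeric(max(model$tissues$label) + 1)
  lut[model$tissues$label + 1] <- model$tissues$sigma
  array(lut[model$labels + 1L], dim(model$labels))
}

# symmetric voxel-center axis about 0 covering [-half, half] plus 1 voxel pad
sym_axis <- function(half, h) {
  n <- 2L * (ceiling(half / h) + 1L)
  (seq_len(n) - (n + 1) / 2) * h
}

# 3-D logical array of center-point membership in an axis-aligned ellipsoid
in_ellipsoid <- function(x, y, z, c0, semi) {
  qx <- ((x - c0[1]) / semi[1])^2
  qy <- ((y - c0[2]) / semi[2])^2
  qz <- ((z - c0[3]) / semi[3])^2
  outer(outer(qx, qy, "+"), qz, "+") <= 1
}

in_elliptic_cylinder <- function(x, y, z, a, b, half_len) {
  q <- outer((x / a)^2, (y / b)^2, "+") <= 1
  outer(q, abs(z) <= half_len, "&")
}

#' Homogeneous elliptical-cylinder phantom
#'
#' Validation geometry: an elliptical cylinder of uniform conductivity, the
#' voxelized analogue of the homogeneous "large man" torso used to derive the
#' original dB/dt-over-E-field conversion ratio. The induced E-field under a
#' uniform axial dB/dt has a closed form against which the solver is checked.
#'
#' @param a,b transverse semi-axes in m (x and y).
#' @param length cylinder length in m (z extent).
#' @param sigma uniform conductivity in S/m.
#' @param resolution isotropic voxel size in mm; at least 8 voxels must span
#'   each semi-axis.
#' @param myocardium surrogate heart region: `"core"` marks a centered
#'   interior ellipsoid (half the transverse semi-axes); `"interior"` marks
#'   the conductor scaled by `1 - margin` (a fixed physical margin from the
#'   staircased air boundary, inside which the solver converges to the
#'   closed form -- voxels at the jagged rim carry the non-vanishing
#'   staircasing overshoot); `"all"` marks the whole conductor.
#' @param margin relative boundary margin used by `myocardium = "interior"`.
#' @param name model identifier.
#' @return a [voxel_model()] with masks `myocardium` and `heart_total`.
#' @examples
#' cyl <- make_homogeneous_cylinder(0.2, 0.125, 0.3, resolution = 8)
#' @export
make_homogeneous_cylinder <- function(a, b = a, length, sigma = 0.23,
                                      resolution = 5,
                                      myocardium = c("core", "interior",
                                                     "all"),
                                      margin = 0.05, name = "cylinder") {
  myocardium <- match.arg(myocardium)
  stopifnot(a > 0, b > 0, length > 0, sigma >= 0)
  h <- resolution / 1000
  if (a / h < 8 || b / h < 8)
    stop("degenerate geometry: fewer than 8 voxels across a semi-axis; ",
         "use a finer resolution")
  x <- sym_axis(a, h); y <- sym_axis(b, h); z <- sym_axis(length / 2, h)
  inside <- in_elliptic_cylinder(x, y, z, a, b, length / 2)
  labels <- array(0L, c(base::length(x), base::length(y), base::length(z)))
  labels[inside] <- 1L
  if (myocardium == "core") {
    myo <- in_ellipsoid(x, y, z, c(0, 0, 0),
                        c(a / 2, b / 2, min(length / 4, a))) & inside
  } else if (myocardium == "interior") {
    s <- 1 - margin
    myo <- in_elliptic_cylinder(x, y, z, s * a, s * b, s * length / 2) &
      inside
  } else {
    myo <- inside
  }
  tis <- tissue_table(c(0L, 1L), c("air", "tissue"), c(0, sigma))
  voxel_model(labels, resolution,
              origin = c(x[1], y[1], z[1]) - h / 2, tissues = tis,
              masks = list(myocardium = myo, heart_total = myo), name = name)
}

#' Torso phantom body parameters
#'
#' Explicit geometric parameterization of the heterogeneous torso phantom:
#' an elliptical-cylinder torso of bulk tissue containing two lung ellipsoids
#' and an ellipsoidal myocardial shell around a blood pool. Defaults describe
#' the package's standard chest-section phantom (a reduced-height torso with
#' a full-size heart), small enough for 1 mm resolution studies on one CPU.
#'
#' Lung x-positions are derived (`lung_center_x = NULL`) so that each lung
#' tip reaches the mid-thickness of the myocardial wall: the lateral
#' myocardium-lung conductivity interface then exists at every resolution and
#' heart scale, which is required to exercise staircasing.
#'
#' @param torso_a,torso_b transverse torso semi-axes (m).
#' @param torso_length torso z extent (m).
#' @param torso_sigma bulk tissue conductivity (S/m); free choice, default
#'   0.23 S/m (muscle/fat average).
#' @param heart_center heart center (m) relative to torso center; offset
#'   left of the midline.
#' @param heart_semiaxes outer semi-axes of the myocardial shell (m).
#' @param wall_thickness myocardial wall thickness (m); the blood pool is the
#'   interior ellipsoid with semi-axes reduced by this amount.
#' @param lung_semiaxes lung ellipsoid semi-axes (m).
#' @param lung_center_x signed x positions of the two lung centers, or NULL
#'   to place them adjacent to the heart automatically.
#' @param lung_center_yz y/z position shared by both lungs (m).
#' @param heart_scale dimensionless enlargement factor applied to the heart
#'   outer semi-axes and wall thickness (cardiomegaly manipulation; volumes
#'   scale with its cube).
#' @param resolution isotropic voxel size in mm.
#' @return list of class `body_params`.
#' @export
body_params <- function(torso_a = 0.09, torso_b = 0.065, torso_length = 0.18,
                        torso_sigma = 0.23,
                        heart_center = c(-0.018, 0.005, 0),
                        heart_semiaxes = c(0.040, 0.034, 0.042),
                        wall_thickness = 0.008,
                        lung_semiaxes = c(0.014, 0.033, 0.055),
                        lung_center_x = NULL,
                        lung_center_yz = c(0.003, 0),
                        heart_scale = 1, resolution = 2) {
  p <- structure(list(torso_a = torso_a, torso_b = torso_b,
                      torso_length = torso_length, torso_sigma = torso_sigma,
                      heart_center = heart_center,
                      heart_semiaxes = heart_semiaxes,
                      wall_thickness = wall_thickness,
                      lung_semiaxes = lung_semiaxes,
                      lung_center_x = lung_center_x,
                      lung_center_yz = lung_center_yz,
                      heart_scale = heart_scale, resolution = resolution),
                 class = "body_params")
  validate_body_params(p)
  p
}

# resolved geometry after applying heart_scale and auto lung placement
resolve_body_params <- function(p) {
  hs <- p$heart_scale
  heart <- p$heart_semiaxes * hs
  wall <- p$wall_thickness * hs
  if (is.null(p$lung_center_x)) {
    # lung tip at mid-wall depth on the heart's far (left) side
    tip <- p$heart_center[1] - heart[1] + wall / 2
    cx <- tip - p$lung_semiaxes[1]
    lung_x <- c(cx, -cx)
  } else {
    lung_x <- p$lung_center_x
  }
  list(heart = heart, blood = heart - wall, wall = wall, lung_x = lung_x)
}

validate_body_params <- function(p) {
  lens <- c(p$torso_a, p$torso_b, p$torso_length, p$heart_semiaxes,
            p$wall_thickness, p$lung_semiaxes, p$heart_scale, p$resolution)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all body-parameter lengths must be positive and finite")
  g <- resolve_body_params(p)
  if (g$wall >= min(g$heart))
    stop("wall thickness must be smaller than the smallest heart semi-axis")
  # analytic containment/overlap screening on sampled ellipsoid surfaces
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  ph <- seq(-pi / 2, pi / 2, length.out = 37)
  sph <- cbind(rep(cos(ph), each = length(th)) * cos(th),
               rep(cos(ph), each = length(th)) * sin(th),
               rep(sin(ph), each = length(th)))
  surf <- function(c0, semi)
    sweep(sweep(sph, 2, semi, "*"), 2, c0, "+")
  in_torso <- function(pt)
    (pt[, 1] / p$torso_a)^2 + (pt[, 2] / p$torso_b)^2 <= 1 &
      abs(pt[, 3]) <= p$torso_length / 2
  hs <- surf(p$heart_center, g$heart)
  if (!all(in_torso(hs))) stop("heart is not fully inside the torso")
  for (s in 1:2) {
    c0 <- c(g$lung_x[s], p$lung_center_yz)
    ls <- surf(c0, p$lung_semiaxes)
    if (!all(in_torso(ls))) stop("lung ", s, " is not fully inside the torso")
    inside_blood <- ((ls[, 1] - p$heart_center[1]) / g$blood[1])^2 +
      ((ls[, 2] - p$heart_center[2]) / g$blood[2])^2 +
      ((ls[, 3] - p$heart_center[3]) / g$blood[3])^2 <= 1
    if (any(inside_blood) ||
        all(abs(c0 - p$heart_center) < g$blood))
      stop("geometry conflict: lung ", s,
           " penetrates the blood pool through the myocardial wall")
  }
  invisible(p)
}

#' Heterogeneous torso phantom
#'
#' Voxelizes the nested torso geometry described by [body_params()]:
#' elliptical-cylinder torso bulk, two lung ellipsoids (0.101 S/m), an
#' ellipsoidal myocardial shell (0.385 S/m) of the stated wall thickness
#' around a blood-pool ellipsoid (0.662 S/m). Voxels take the innermost shape
#' containing their center (blood > myocardium > lung > torso), so
#' myocardium-lung and myocardium-blood interfaces exist by construction.
#'
#' @param params a [body_params()] object.
#' @param name model identifier.
#' @return a [voxel_model()] with masks `myocardium` (shell label) and
#'   `heart_total` (shell plus blood pool).
#' @examples
#' ph <- make_torso_phantom(body_params(resolution = 4))
#' @export
make_torso_phantom <- function(params, name = "torso") {
  stopifnot(inherits(params, "body_params"))
  validate_body_params(params)
  g <- resolve_body_params(params)
  h <- params$resolution / 1000
  x <- sym_axis(params$torso_a, h)
  y <- sym_axis(params$torso_b, h)
  z <- sym_axis(params$torso_length / 2, h)
  torso <- in_elliptic_cylinder(x, y, z, params$torso_a, params$torso_b,
                                params$torso_length / 2)
  heart <- in_ellipsoid(x, y, z, params$heart_center, g$heart)
  blood <- in_ellipsoid(x, y, z, params$heart_center, g$blood)
  lung1 <- in_ellipsoid(x, y, z, c(g$lung_x[1], params$lung_center_yz),
                        params$lung_semiaxes)
  lung2 <- in_ellipsoid(x, y, z, c(g$lung_x[2], params$lung_center_yz),
                        params$lung_semiaxes)
  lung <- lung1 | lung2
  if (any(lung & blood))
    stop("geometry conflict: lung voxels overlap the blood pool")
  labels <- array(0L, dim(torso))
  labels[torso] <- 1L
  labels[lung & torso] <- 2L
  labels[heart & torso] <- 3L
  labels[blood & torso] <- 4L
  voxel_model(labels, params$resolution,
              origin = c(x[1], y[1], z[1]) - h / 2,
              tissues = default_tissue_table(params$torso_sigma),
              masks = list(myocardium = labels == 3L,
                           heart_total = labels == 3L | labels == 4L),
              name = name)
}

#' Body parameters from anthropometry
#'
#' Maps height and weight to torso-phantom geometry: torso length is 30% of
#' height; the torso holds 45% of body volume at density 1050 kg/m3 with a
#' 0.7 transverse aspect ratio; heart dimensions scale linearly with height
#' about a 1.70 m reference adult. Lungs are placed adjacent to the heart
#' (see [body_params()]).
#'
#' @param height stature in m.
#' @param weight body mass in kg.
#' @param heart_scale heart enlargement factor.
#' @param resolution voxel size in mm.
#' @return a [body_params()] object.
#' @export
body_params_from_anthropometry <- function(height, weight, heart_scale = 1,
                                           resolution = 5) {
  stopifnot(height > 0, weight > 0)
  L <- 0.30 * height
  vol <- 0.45 * weight / 1050
  a <- sqrt(vol / (0.70 * pi * L))
  b <- 0.70 * a
  s <- height / 1.70
  body_params(torso_a = a, torso_b = b, torso_length = L,
              heart_center = c(-0.20 * a, 0.08 * b, 0),
              heart_semiaxes = s * c(0.047, 0.040, 0.050),
              wall_thickness = 0.009 * s,
              lung_semiaxes = c(min(0.16 * a, 0.030), 0.50 * b, 0.33 * L),
              lung_center_yz = c(0.05 * b, 0),
              heart_scale = heart_scale, resolution = resolution)
}

#' Generate a synthetic body-model population
#'
#' Draws phantom parameters uniformly from stated ranges (heights 1.53-1.90 m
#' and weights 52-120 kg by default, the adult span used in gradient-coil
#' dosimetry studies) with a seeded generator, and voxelizes each body.
#'
#' @param n number of models (>= 1).
#' @param seed integer RNG seed; identical seeds give identical model lists.
#' @param ranges named list of `c(min, max)` ranges for `height` (m),
#'   `weight` (kg) and `heart_scale`.
#' @param resolution voxel size in mm for every model.
#' @return list of [voxel_model()] objects named `body01`, `body02`, ...
#' @examples
#' pop <- make_population(2, seed = 7, resolution = 8)
#' @export
make_population <- function(n, seed,
                            ranges = list(height = c(1.53, 1.90),
                                          weight = c(52, 120),
                                          heart_scale = c(1, 1)),
                            resolution = 5) {
  stopifnot(n >= 1)
  rng <- function(nm, default) if (is.null(ranges[[nm]])) default else {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("invalid range for ", nm)
    r
  }
  hr <- rng("height", c(1.53, 1.90))
  wr <- rng("weight", c(52, 120))
  sr <- rng("heart_scale", c(1, 1))
  # fail before generation if any corner of the parameter box is infeasible
  for (hh in hr) for (ww in wr) for (ss in sr)
    body_params_from_anthropometry(hh, ww, ss, resolution)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- data.frame(height = runif(n, hr[1], hr[2]),
                      weight = runif(n, wr[1], wr[2]),
                      heart_scale = runif(n, sr[1], sr[2]))
  models <- vector("list", n)
  for (i in seq_len(n)) {
    p <- body_params_from_anthropometry(draws$height[i], draws$weight[i],
                                        draws$heart_scale[i], resolution)
    models[[i]] <- make_torso_phantom(p, name = sprintf("body%02d", i))
    models[[i]]$anthropometry <- draws[i, ]
  }
  names(models) <- sprintf("body%02d", seq_len(n))
  models
}
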