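# Gradient coils as wire-loop sets.
#
# B and A are computed with exact finite-straight-segment closed forms
# (Coulomb gauge for A), summed over loops weighted by signed current; no
# numerical quadrature. Loops are discretized at >= 72 segments per turn.
# With real-valued tissue conductivity in the magneto-quasistatic regime the
# induced E is in phase with dB/dt, so all field computations are done with
# real arithmetic at the instant of peak slew; the drive frequency cancels
# from every dB/dt-over-E ratio and only matters for effective stimulus
# durations.

#' Wire-loop coil model
#'
#' @param loops list of loops, each a list with `vertices` (k x 3 matrix of
#'   positions in m, implicitly closed, k >= 3) and `current` (signed
#'   A-turns).
#' @param axis gradient axis this coil produces: `"x"`, `"y"` or `"z"`.
#' @param inner_diameter,length coil geometric metadata in m. Realistic
#'   presets keep the inner diameter in \[0.64, 0.92\] m and the length in
#'   \[1.06, 1.60\] m; pass `override = TRUE` to exceed them.
#' @param name coil identifier.
#' @param override allow geometry outside the realistic preset ranges.
#' @return object of class `coil_model`.
#' @export
coil_model <- function(loops, axis, inner_diameter, length, name = "coil",
                       override = FALSE) {
  axis <- match.arg(tolower(axis), c("x", "y", "z"))
  for (lp in loops) {
    v <- lp$vertices
    if (!is.matrix(v) || ncol(v) != 3 || nrow(v) < 3)
      stop("each loop needs a k x 3 vertex matrix with k >= 3")
    if (!all(is.finite(v)) || !is.finite(lp$current))
      stop("loop vertices and currents must be finite")
  }
  if (!override) {
    if (inner_diameter < 0.64 || inner_diameter > 0.92)
      stop("inner diameter ", inner_diameter, " m outside the realistic ",
           "range [0.64, 0.92] m; set override = TRUE to allow")
    if (length < 1.06 || length > 1.60)
      stop("coil length ", length, " m outside the realistic range ",
           "[1.06, 1.60] m; set override = TRUE to allow")
  }
  structure(list(loops = loops, axis = axis,
                 inner_diameter = inner_diameter, length = length,
                 name = name),
            class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  cat("coil_model '", x$name, "': axis ", x$axis, ", ",
      length(x$loops), " loops, id ", x$inner_diameter, " m, length ",
      x$length, " m\n", sep = "")
  invisible(x)
}

# flatten loops to segment arrays (closing edge added)
coil_segments <- function(coil) {
  starts <- ends <- list()
  currents <- loop_id <- list()
  for (i in seq_along(coil$loops)) {
    v <- coil$loops[[i]]$vertices
    if (!isTRUE(all.equal(v[1, ], v[nrow(v), ], tolerance = 1e-12)))
      v <- rbind(v, v[1, ])
    k <- nrow(v) - 1
    starts[[i]] <- v[seq_len(k), , drop = FALSE]
    ends[[i]] <- v[seq_len(k) + 1, , drop = FALSE]
    currents[[i]] <- rep(coil$loops[[i]]$current, k)
    loop_id[[i]] <- rep(i, k)
  }
  list(p1 = do.call(rbind, starts), p2 = do.call(rbind, ends),
       current = unlist(currents), loop_id = as.integer(unlist(loop_id)))
}

field_samples <- function(points, values, kind = c("B", "A", "dAdt")) {
  structure(list(points = points, values = values,
                 kind = match.arg(kind)),
            class = "field_samples")
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  points
}

#' Magnetic field of a coil (Biot-Savart)
#'
#' Exact finite-segment Biot-Savart sum over all loops, weighted by signed
#' currents. Field points must stay at least `min_dist` (default 1 mm) away
#' from every wire segment; closer points raise a singular-evaluation error
#' naming the offending loop.
#'
#' @param source a [coil_model()], [gradient_set()] member or ideal field
#'   from [make_ideal_field()].
#' @param points n x 3 matrix of positions in m.
#' @param min_dist minimum point-to-wire distance in m.
#' @return a `field_samples` object with `kind = "B"` (tesla, per unit of
#'   the stored loop currents).
#' @export
biot_savart_B <- function(source, points, min_dist = 1e-3) {
  UseMethod("biot_savart_B")
}

#' @export
biot_savart_B.coil_model <- function(source, points, min_dist = 1e-3) {
  points <- as_points(points)
  seg <- coil_segments(source)
  out <- segment_fields_cpp(seg$p1, seg$p2, seg$current, seg$loop_id,
                            points, TRUE, FALSE, min_dist)
  field_samples(points, out$B, "B")
}

#' Magnetic vector potential of a coil
#'
#' Exact finite-straight-segment closed form in the Coulomb gauge, summed
#' over segments. The time derivative dA/dt at peak slew is obtained by
#' scaling A (see [drive_scale()]); the sinusoidal drive frequency cancels.
#'
#' @inheritParams biot_savart_B
#' @return a `field_samples` object with `kind = "A"` (tesla meter per unit
#'   current).
#' @export
vector_potential_A <- function(source, points, min_dist = 1e-3) {
  UseMethod("vector_potential_A")
}

#' @export
vector_potential_A.coil_model <- function(source, points, min_dist = 1e-3) {
  points <- as_points(points)
  seg <- coil_segments(source)
  out <- segment_fields_cpp(seg$p1, seg$p2, seg$current, seg$loop_id,
                            points, FALSE, TRUE, min_dist)
  field_samples(points, out$A, "A")
}

circle_loop <- function(R, z0, current, n_seg = 72) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  list(vertices = cbind(R * cos(th), R * sin(th), rep(z0, n_seg)),
       current = current)
}

# saddle: arc at z_a traversed phi- -> phi+, axial legs, return arc at z_b
saddle_loop <- function(R, z_a, z_b, phi_c, half_ang, current, n_arc = 24) {
  f <- seq(phi_c - half_ang, phi_c + half_ang, length.out = n_arc + 1)
  a1 <- cbind(R * cos(f), R * sin(f), rep(z_a, n_arc + 1))
  a2 <- cbind(R * cos(rev(f)), R * sin(rev(f)), rep(z_b, n_arc + 1))
  list(vertices = rbind(a1, a2), current = current)
}

rotate_z <- function(v, angle) {
  Rm <- matrix(c(cos(angle), sin(angle), 0,
                 -sin(angle), cos(angle), 0,
                 0, 0, 1), 3, 3)
  v %*% t(Rm)
}

#' Idealized per-axis gradient coil generator
#'
#' Builds a wire-loop gradient coil for one axis: a Maxwell pair for z
#' (opposed circular loops at the optimal half-separation sqrt(3)/2 R, or
#' closer if the length budget requires) and a Golay saddle family for x/y
#' (the y coil is the x coil rotated 90 degrees about z). With
#' `shielded = TRUE`, a geometrically scaled copy of the winding at
#' `shield_scale` times the primary radius carries opposing current scaled by
#' `(R/Rs)^3`, cancelling the leading far-field multipole.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param inner_diameter primary winding diameter in m.
#' @param length overall coil length (wire z extent) in m.
#' @param shielded add the concentric shield winding.
#' @param turns number of turns per loop (scales currents).
#' @param shield_scale shield-to-primary radius ratio (> 1).
#' @param n_seg segments per full turn (>= 72 for circles).
#' @param override allow geometry outside the realistic preset ranges.
#' @param name coil identifier (default derived from the arguments).
#' @return a [coil_model()].
#' @examples
#' zc <- make_axis_coil("z", 0.70, 1.40)
#' @export
make_axis_coil <- function(axis = c("x", "y", "z"), inner_diameter = 0.70,
                           length = 1.40, shielded = TRUE, turns = 1,
                           shield_scale = 1.25, n_seg = 72,
                           override = FALSE, name = NULL) {
  axis <- match.arg(tolower(axis[1]), c("x", "y", "z"))
  R <- inner_diameter / 2
  if (shield_scale <= 1)
    stop("shield radius must exceed the primary radius (shield_scale > 1)")
  rho <- if (shielded) shield_scale else 1
  zmax <- (length / 2) / rho    # primary wire extent; shield reaches length/2
  i_shield <- -turns / shield_scale^3
  loops <- list()
  if (axis == "z") {
    zp <- min(sqrt(3) / 2 * R, 0.9 * zmax)
    loops <- list(circle_loop(R, +zp, +turns, n_seg),
                  circle_loop(R, -zp, -turns, n_seg))
    if (shielded) {
      Rs <- R * shield_scale
      loops <- c(loops,
                 list(circle_loop(Rs, +zp * rho, i_shield, n_seg),
                      circle_loop(Rs, -zp * rho, -i_shield, n_seg)))
    }
  } else {
    z2 <- zmax
    z1 <- 0.35 * zmax
    half <- pi / 3                      # 120 degree arcs
    n_arc <- max(24, ceiling(n_seg / 3))
    build <- function(Rr, zz1, zz2, amp) {
      list(saddle_loop(Rr, zz1, zz2, 0, half, +amp, n_arc),
           saddle_loop(Rr, zz1, zz2, pi, half, -amp, n_arc),
           saddle_loop(Rr, -zz1, -zz2, 0, half, +amp, n_arc),
           saddle_loop(Rr, -zz1, -zz2, pi, half, -amp, n_arc))
    }
    loops <- build(R, z1, z2, turns)
    if (shielded)
      loops <- c(loops, build(R * shield_scale, z1 * rho, z2 * rho,
                              i_shield))
    if (axis == "y")
      loops <- lapply(loops, function(lp) {
        lp$vertices <- rotate_z(lp$vertices, pi / 2)
        lp
      })
  }
  if (is.null(name))
    name <- sprintf("%s%s_id%0.2f_L%0.2f", toupper(axis),
                    if (shielded) "s" else "", inner_diameter, length)
  coil_model(loops, axis, inner_diameter, length, name = name,
             override = override)
}

#' Full three-axis gradient set
#'
#' @inheritParams make_axis_coil
#' @return list of class `gradient_set` with elements `x`, `y`, `z`.
#' @export
gradient_set <- function(inner_diameter = 0.70, length = 1.40,
                         shielded = TRUE, turns = 1, override = FALSE,
                         name = NULL) {
  if (is.null(name))
    name <- sprintf("GC_id%0.2f_L%0.2f", inner_diameter, length)
  out <- lapply(c("x", "y", "z"), make_axis_coil,
                inner_diameter = inner_diameter, length = length,
                shielded = shielded, turns = turns, override = override)
  names(out) <- c("x", "y", "z")
  structure(c(out, list(name = name)), class = "gradient_set")
}

#' Ideal analytic field source
#'
#' Synthetic sources with exact vector potentials, used to bypass
#' Biot-Savart in validation scenarios:
#' * `uniform_B`: Bz = B0 everywhere, A = (B0/2)(-y, x, 0); curl A = B
#'   exactly.
#' * `uniform_gradient`: the gradient part Bz = G z with
#'   A = G(-yz/2, xz/2, 0). The reported B is the idealized (0, 0, G z);
#'   the full curl of A additionally carries the divergence-free transverse
#'   terms (-Gx/2, -Gy/2, 0), which any physical z-gradient must have.
#'
#' @param kind `"uniform_B"` or `"uniform_gradient"`.
#' @param magnitude B0 in T (uniform_B) or G in T/m (uniform_gradient), per
#'   unit drive.
#' @return object of class `ideal_field`.
#' @export
make_ideal_field <- function(kind = c("uniform_B", "uniform_gradient"),
                             magnitude = 1) {
  kind <- match.arg(kind)
  stopifnot(is.finite(magnitude))
  structure(list(kind = kind, magnitude = magnitude,
                 name = paste0("ideal_", kind), axis = "z"),
            class = "ideal_field")
}

#' @export
biot_savart_B.ideal_field <- function(source, points, min_dist = 1e-3) {
  points <- as_points(points)
  n <- nrow(points)
  v <- if (source$kind == "uniform_B") {
    cbind(rep(0, n), rep(0, n), rep(source$magnitude, n))
  } else {
    cbind(rep(0, n), rep(0, n), source$magnitude * points[, 3])
  }
  field_samples(points, v, "B")
}

#' @export
vector_potential_A.ideal_field <- function(source, points, min_dist = 1e-3) {
  points <- as_points(points)
  v <- if (source$kind == "uniform_B") {
    source$magnitude / 2 * cbind(-points[, 2], points[, 1], 0)
  } else {
    source$magnitude / 2 *
      cbind(-points[, 2] * points[, 3], points[, 1] * points[, 3], 0)
  }
  field_samples(points, v, "A")
}

#' Gradient efficiency at isocenter
#'
#' Central finite difference (1 mm step) of the gradient-defining Bz
#' derivative at isocenter: dBz/dx, dBz/dy or dBz/dz according to the coil's
#' axis, per unit of the stored currents.
#'
#' @param source coil or ideal field.
#' @param step finite-difference step in m.
#' @return efficiency in T/m per unit current.
#' @export
gradient_efficiency <- function(source, step = 1e-3) {
  UseMethod("gradient_efficiency")
}

#' @export
gradient_efficiency.coil_model <- function(source, step = 1e-3) {
  d <- switch(source$axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  pts <- rbind(d * step, -d * step)
  B <- biot_savart_B(source, pts)$values
  g <- (B[1, 3] - B[2, 3]) / (2 * step)
  if (abs(g) < 1e-12)
    stop("degenerate coil: |G_eff| < 1e-12 T/m at isocenter")
  g
}

#' @export
gradient_efficiency.ideal_field <- function(source, step = 1e-3) {
  if (source$kind == "uniform_gradient") return(source$magnitude)
  stop("degenerate coil: a uniform B field has no gradient at isocenter")
}

#' Drive specification
#'
#' @param slew gradient slew rate in T/m/s (total across the driven axes).
#'   For `uniform_B` ideal sources this value is read as dB/dt in T/s.
#' @param frequency sinusoidal drive frequency in Hz (only relevant for
#'   effective stimulus durations; it cancels from all peak-slew fields).
#' @param axes driven axis combination: `"x"`, `"y"`, `"z"` or `"xyz"`.
#' @param combination_rule split of the total slew across simultaneous axes;
#'   `"rss"` drives each of the three axes at `slew / sqrt(3)` in phase.
#' @return object of class `drive_spec`.
#' @export
drive_spec <- function(slew = 100, frequency = 1000, axes = "z",
                       combination_rule = "rss") {
  stopifnot(slew > 0, frequency > 0)
  axes <- match.arg(tolower(axes), c("x", "y", "z", "xyz"))
  combination_rule <- match.arg(combination_rule, "rss")
  structure(list(slew = slew, frequency = frequency, axes = axes,
                 combination_rule = combination_rule),
            class = "drive_spec")
}

#' Field scale factor for a drive
#'
#' Per-unit-current fields are converted to peak-slew fields by
#' `slew / G_eff`: with a sinusoidal current of amplitude
#' `I0 = S / (omega G_eff)`, peak dA/dt equals `A_unit * S / G_eff` and peak
#' dB/dt equals `|B_unit| * S / G_eff`; the frequency cancels.
#'
#' @param source coil or ideal field.
#' @param slew slew rate in T/m/s (dB/dt in T/s for `uniform_B`).
#' @return dimensionless scale factor (1/A units).
#' @export
drive_scale <- function(source, slew) {
  if (inherits(source, "ideal_field") && source$kind == "uniform_B")
    return(slew / source$magnitude)
  slew / gradient_efficiency(source)
}

# resolve (source, drive) into the per-axis sources and slews actually driven
driven_axes <- function(source, drive) {
  if (inherits(source, "gradient_set")) {
    ax <- if (drive$axes == "xyz") c("x", "y", "z") else drive$axes
    slews <- rep(if (drive$axes == "xyz") drive$slew / sqrt(3)
                 else drive$slew, length(ax))
    list(sources = unname(source[ax]), slews = slews)
  } else {
    list(sources = list(source), slews = drive$slew)
  }
}

#' IEC compliance volume
#'
#' Cylinder of 20 cm radius along the bore axis on which the IEC dB/dt limit
#' is evaluated.
#'
#' @param radius cylinder radius in m.
#' @param z_extent `c(z_min, z_max)` in m; defaults to the coil wire extent
#'   when omitted in [compliance_peak_dBdt()].
#' @param spacing sample grid spacing in m (<= 0.01 recommended).
#' @return object of class `compliance_volume`.
#' @export
compliance_volume <- function(radius = 0.20, z_extent = NULL,
                              spacing = 0.01) {
  stopifnot(radius > 0, spacing > 0)
  if (!is.null(z_extent) && z_extent[1] >= z_extent[2])
    stop("z_min must be smaller than z_max")
  structure(list(radius = radius, z_extent = z_extent, spacing = spacing),
            class = "compliance_volume")
}

coil_z_extent <- function(source) {
  if (inherits(source, "gradient_set"))
    return(range(unlist(lapply(source[c("x", "y", "z")], coil_z_extent))))
  if (inherits(source, "ideal_field")) return(c(-0.5, 0.5))
  range(unlist(lapply(source$loops, function(lp) lp$vertices[, 3])))
}

cv_sample_points <- function(cv, source) {
  zext <- if (is.null(cv$z_extent)) coil_z_extent(source) else cv$z_extent
  s <- cv$spacing
  xy <- seq(-cv$radius, cv$radius, by = s)
  g <- expand.grid(x = xy, y = xy)
  g <- g[g$x^2 + g$y^2 <= cv$radius^2, ]
  z <- seq(zext[1], zext[2], by = s)
  pts <- cbind(rep(g$x, length(z)), rep(g$y, length(z)),
               rep(z, each = nrow(g)))
  if (nrow(pts) == 0) stop("empty compliance-volume sample grid")
  pts
}

#' Peak dB/dt over the IEC compliance volume
#'
#' Maximum |B| per unit current over the sampled compliance cylinder, scaled
#' by `slew / G_eff`. For an axis combination the per-axis fields (each at
#' `slew / sqrt(3)` under the root-sum-square rule) are summed in phase
#' before taking |B|. The result is invariant to the coil current amplitude.
#'
#' @param source a [coil_model()], [gradient_set()] or [make_ideal_field()].
#' @param drive a [drive_spec()].
#' @param cv a [compliance_volume()].
#' @return peak dB/dt in T/s.
#' @examples
#' compliance_peak_dBdt(make_ideal_field("uniform_gradient", 1),
#'                      drive_spec(100, axes = "z"),
#'                      compliance_volume(z_extent = c(-0.5, 0.5)))
#' @export
compliance_peak_dBdt <- function(source, drive = drive_spec(),
                                 cv = compliance_volume()) {
  pts <- cv_sample_points(cv, source)
  da <- driven_axes(source, drive)
  Btot <- matrix(0, nrow(pts), 3)
  for (i in seq_along(da$sources)) {
    sc <- drive_scale(da$sources[[i]], da$slews[i])
    Btot <- Btot + biot_savart_B(da$sources[[i]], pts)$values * sc
  }
  max(sqrt(rowSums(Btot^2)))
}
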