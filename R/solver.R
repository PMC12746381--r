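# Magneto-quasistatic scalar-potential solver.
#
# Unknowns are cell-centered potentials on conducting voxels. The discrete
# conservation law div(sigma (grad phi + dA/dt)) = 0 uses a 7-point stencil
# with harmonic-mean face conductivities; faces with a zero-sigma neighbor
# carry zero flux, which imposes the insulating boundary naturally. The
# system is symmetric positive semi-definite and is solved by Jacobi-
# preconditioned conjugate gradients; the nullspace (one constant per
# connected conductor component) is fixed by mean-zero phi per component.

#' Solver configuration
#'
#' @param rel_tolerance relative residual ||r||/||b|| for convergence.
#' @param max_iterations conjugate-gradient iteration cap.
#' @param preconditioner only `"jacobi"` (diagonal) is implemented.
#' @param reference_constraint only `"mean_zero"` (per conductor component).
#' @return object of class `solve_config`.
#' @export
solve_config <- function(rel_tolerance = 1e-8, max_iterations = 50000,
                         preconditioner = "jacobi",
                         reference_constraint = "mean_zero") {
  stopifnot(rel_tolerance > 0, rel_tolerance < 1, max_iterations >= 1)
  preconditioner <- match.arg(preconditioner, "jacobi")
  reference_constraint <- match.arg(reference_constraint, "mean_zero")
  structure(list(rel_tolerance = rel_tolerance,
                 max_iterations = max_iterations,
                 preconditioner = preconditioner,
                 reference_constraint = reference_constraint),
            class = "solve_config")
}

shift_arr <- function(a, axis, by) {
  # shift array contents by +1/-1 along axis, padding with the edge value
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - by
  src[src < 1] <- 1
  src[src > d[axis]] <- d[axis]
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

#' Finite-difference system for a voxel model
#'
#' Precomputes the sparse conductance Laplacian, face lists and conductor
#' component labels for [solve_scalar_potential()]. Build once per model and
#' reuse across drives and landmarks (the matrix depends on the conductivity
#' grid only).
#'
#' @param model a [voxel_model()].
#' @return list of class `fd_system`.
#' @export
fd_system <- function(model) {
  S <- sigma_grid(model)
  d <- dim(S)
  h <- model$spacing / 1000
  cond <- S > 0
  nu <- sum(cond)
  if (nu == 0) stop("model has no conducting voxel")
  umap <- array(0L, d)
  umap[cond] <- seq_len(nu)
  faces <- vector("list", 3)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    keep <- slice.index(S, ax) < d[ax]
    Sup <- shift_arr(S, ax, -1)           # neighbor at +1 along ax
    ok <- keep & cond & Sup > 0
    lin <- which(ok)
    w <- 2 * S[lin] * Sup[lin] / (S[lin] + Sup[lin])
    faces[[ax]] <- list(lin_low = lin, lin_up = lin + strides[ax],
                        p = umap[lin], q = umap[lin + strides[ax]], w = w)
  }
  i <- c(unlist(lapply(faces, `[[`, "p")), unlist(lapply(faces, `[[`, "q")))
  j <- c(unlist(lapply(faces, `[[`, "q")), unlist(lapply(faces, `[[`, "p")))
  w2 <- c(unlist(lapply(faces, `[[`, "w")), unlist(lapply(faces, `[[`, "w")))
  L <- Matrix::sparseMatrix(i = c(i, i), j = c(j, i), x = c(-w2, w2),
                            dims = c(nu, nu))
  dg <- Matrix::diag(L)
  comp <- label_components_cpp(cond, as.integer(d))
  structure(list(L = L, diag = dg, faces = faces, umap = umap, cond = cond,
                 comp_of_unknown = comp[cond], n_unknown = nu, dims = d,
                 h = h),
            class = "fd_system")
}

pcg <- function(L, b, dg, rtol, maxit) {
  bnorm <- sqrt(sum(b^2))
  x <- numeric(length(b))
  if (bnorm == 0)
    return(list(x = x, iterations = 0L, rel_residual = 0))
  m <- ifelse(dg > 0, dg, 1)
  r <- b
  z <- r / m
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(L %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rn <- sqrt(sum(r^2))
    if (rn <= rtol * bnorm)
      return(list(x = x, iterations = it, rel_residual = rn / bnorm))
    z <- r / m
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf(
    "conjugate gradients did not converge in %d iterations (rel residual %.3e)",
    maxit, rn / bnorm))
}

grid_field_values <- function(dAdt, sys) {
  # accept a grid_field (list of 3 arrays) congruent with the model grid
  if (inherits(dAdt, "grid_field")) {
    v <- dAdt$values
  } else if (is.list(dAdt) && length(dAdt) == 3) {
    v <- dAdt
  } else {
    stop("dAdt must be a grid_field sampled at the model's voxel centers")
  }
  for (k in 1:3)
    if (!identical(dim(v[[k]]), sys$dims))
      stop("dAdt grid dimensions do not match the model grid")
  v
}

#' Solve for the scalar potential
#'
#' Solves `div(sigma (grad phi + dA/dt)) = 0` with zero normal current at
#' conductor boundaries for the given excitation, to the configured relative
#' residual. Disconnected conductor components are handled independently
#' (mean-zero potential each).
#'
#' @param model a [voxel_model()].
#' @param dAdt a `grid_field` (see [dAdt_grid()]) of peak dA/dt values (V/m)
#'   at the voxel centers of the model grid.
#' @param config a [solve_config()].
#' @param system optional precomputed [fd_system()] for `model`.
#' @return list of class `potential_grid`: `phi` (V, full-grid array, zero
#'   outside the conductor), `iterations`, `rel_residual`.
#' @export
solve_scalar_potential <- function(model, dAdt, config = solve_config(),
                                   system = NULL) {
  sys <- if (is.null(system)) fd_system(model) else system
  v <- grid_field_values(dAdt, sys)
  b <- numeric(sys$n_unknown)
  for (ax in 1:3) {
    f <- sys$faces[[ax]]
    df <- 0.5 * (v[[ax]][f$lin_low] + v[[ax]][f$lin_up])
    contrib <- sys$h * f$w * df
    b <- b + tabulate2(f$p, contrib, sys$n_unknown) -
      tabulate2(f$q, contrib, sys$n_unknown)
  }
  sol <- pcg(sys$L, b, sys$diag, config$rel_tolerance,
             config$max_iterations)
  x <- sol$x
  # fix the nullspace: mean-zero phi over each conductor component
  mz <- tapply(x, sys$comp_of_unknown, mean)
  x <- x - as.numeric(mz[as.character(sys$comp_of_unknown)])
  phi <- array(0, sys$dims)
  phi[sys$cond] <- x
  structure(list(phi = phi, iterations = sol$iterations,
                 rel_residual = sol$rel_residual, model_name = model$name),
            class = "potential_grid")
}

# sum `vals` into bins given by positive integer index `idx`
tabulate2 <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Induced electric field from potential and excitation
#'
#' Computes `E = -dA/dt - grad(phi)` at voxel centers. The potential
#' gradient along each axis is the mean of the two face differences; at
#' insulating faces the face gradient is set to `-dA/dt` so the normal E
#' vanishes there, consistent with the zero-flux discretization. E is zeroed
#' outside the conductor.
#'
#' @param phi a `potential_grid` from [solve_scalar_potential()].
#' @param dAdt the same excitation passed to the solve.
#' @param model the same [voxel_model()].
#' @param landmark_z body landmark position recorded in the map (m).
#' @param drive optional [drive_spec()] recorded in the map.
#' @return list of class `efield_map`: `vectors` (list of Ex, Ey, Ez
#'   arrays, V/m), `magnitude` (V/m), plus provenance fields.
#' @export
compute_E <- function(phi, dAdt, model, landmark_z = 0, drive = NULL) {
  S <- sigma_grid(model)
  d <- dim(S)
  if (!identical(dim(phi$phi), d)) stop("potential grid mismatch")
  h <- model$spacing / 1000
  cond <- S > 0
  v <- grid_field_values(dAdt, list(dims = d))
  vec <- vector("list", 3)
  names(vec) <- c("x", "y", "z")
  for (ax in 1:3) {
    p_up <- shift_arr(phi$phi, ax, -1)
    p_dn <- shift_arr(phi$phi, ax, +1)
    c_up <- shift_arr(cond, ax, -1) & slice.index(S, ax) < d[ax]
    c_dn <- shift_arr(cond, ax, +1) & slice.index(S, ax) > 1
    g_up <- ifelse(cond & c_up, (p_up - phi$phi) / h, -v[[ax]])
    g_dn <- ifelse(cond & c_dn, (phi$phi - p_dn) / h, -v[[ax]])
    Ek <- (-v[[ax]] - 0.5 * (g_up + g_dn))
    Ek[!cond] <- 0
    vec[[ax]] <- Ek
  }
  mag <- sqrt(vec$x^2 + vec$y^2 + vec$z^2)
  structure(list(vectors = vec, magnitude = mag, phi = phi$phi, dAdt = v,
                 model_name = model$name, spacing = model$spacing,
                 landmark_z = landmark_z, drive = drive),
            class = "efield_map")
}

#' @export
print.efield_map <- function(x, ...) {
  cat("efield_map for '", x$model_name, "': max |E| = ",
      signif(max(x$magnitude), 4), " V/m\n", sep = "")
  invisible(x)
}

#' Discrete current-conservation residual
#'
#' Validation diagnostic: maximum net discrete current over interior
#' conducting cells (all six neighbors conducting), normalized by the mean
#' face current magnitude. For a converged solve this is at the level of the
#' solver tolerance; for a field that skips the potential solve (E = -dA/dt
#' with heterogeneous sigma) it is large.
#'
#' @param E an [compute_E()] result.
#' @param model the [voxel_model()] it was computed on.
#' @param use_phi use the stored potential for face gradients (default);
#'   otherwise faces use averaged cell-center E.
#' @return dimensionless residual.
#' @export
current_conservation_residual <- function(E, model,
                                          use_phi = !is.null(E$phi)) {
  sys <- fd_system(model)
  h <- sys$h
  net <- numeric(sys$n_unknown)
  flux_abs <- 0
  n_face <- 0
  for (ax in 1:3) {
    f <- sys$faces[[ax]]
    if (use_phi && !is.null(E$phi)) {
      df <- 0.5 * (E$dAdt[[ax]][f$lin_low] + E$dAdt[[ax]][f$lin_up])
      En <- -df - (E$phi[f$lin_up] - E$phi[f$lin_low]) / h
    } else {
      Ek <- E$vectors[[ax]]
      En <- 0.5 * (Ek[f$lin_low] + Ek[f$lin_up])
    }
    J <- f$w * En
    net <- net + tabulate2(f$p, J, sys$n_unknown) -
      tabulate2(f$q, J, sys$n_unknown)
    flux_abs <- flux_abs + sum(abs(J))
    n_face <- n_face + length(J)
  }
  # interior cells: all six face-neighbors conducting
  deg <- numeric(sys$n_unknown)
  for (ax in 1:3) {
    f <- sys$faces[[ax]]
    deg <- deg + tabulate2(f$p, rep(1, length(f$p)), sys$n_unknown) +
      tabulate2(f$q, rep(1, length(f$q)), sys$n_unknown)
  }
  interior <- deg == 6
  if (!any(interior)) return(0)
  max(abs(net[interior])) / (flux_abs / n_face)
}

#' Sample peak dA/dt on a model grid
#'
#' Evaluates the source vector potential at the model's voxel centers,
#' scaled to peak slew (see [drive_scale()]), summing driven axes for axis
#' combinations. Coil fields are evaluated on a coarse auxiliary lattice and
#' interpolated trilinearly (A is smooth away from the windings); ideal
#' fields are evaluated exactly.
#'
#' @param source coil, gradient set or ideal field.
#' @param model a [voxel_model()].
#' @param drive a [drive_spec()].
#' @param interp_spacing coarse lattice spacing in m; set to 0 to force
#'   exact evaluation at every voxel center.
#' @return object of class `grid_field` (list of 3 arrays, V/m).
#' @export
dAdt_grid <- function(source, model, drive = drive_spec(),
                      interp_spacing = 0.008) {
  da <- driven_axes(source, drive)
  caches <- make_A_caches(da$sources, model, c(0, 0), interp_spacing)
  dAdt_from_caches(model, da, caches, interp_spacing)
}

# coarse vector-potential lattices, one per driven source, covering the
# model grid over the full range of landmark offsets
make_A_caches <- function(sources, model, offset_range, spacing) {
  ax <- grid_axes(model)
  lapply(sources, function(src) {
    if (inherits(src, "ideal_field") || spacing <= 0) return(NULL)
    cgrid <- function(r) {
      lo <- r[1] - spacing
      hi <- r[2] + spacing
      seq(lo, hi, length.out = max(2, ceiling((hi - lo) / spacing) + 1))
    }
    cx <- cgrid(range(ax$x))
    cy <- cgrid(range(ax$y))
    cz <- cgrid(range(ax$z) + offset_range)
    pts <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
    A <- vector_potential_A(src, pts)$values
    list(cx = cx, cy = cy, cz = cz,
         A = lapply(1:3, function(k)
           array(A[, k], c(length(cx), length(cy), length(cz)))))
  })
}

dAdt_from_caches <- function(model, da, caches, interp_spacing) {
  d <- dim(model$labels)
  tot <- list(array(0, d), array(0, d), array(0, d))
  for (i in seq_along(da$sources)) {
    src <- da$sources[[i]]
    sc <- drive_scale(src, da$slews[i])
    if (is.null(caches[[i]])) {
      A <- vector_potential_A(src, voxel_centers(model))$values
      for (k in 1:3) tot[[k]] <- tot[[k]] + array(A[, k], d) * sc
    } else {
      Ak <- trilinear_from_cache(caches[[i]], model)
      for (k in 1:3) tot[[k]] <- tot[[k]] + Ak[[k]] * sc
    }
  }
  structure(list(values = tot, dims = d), class = "grid_field")
}

trilinear_from_cache <- function(cache, model) {
  ax <- grid_axes(model)
  d <- dim(model$labels)
  dc <- c(length(cache$cx), length(cache$cy), length(cache$cz))
  loc <- function(v, cv) {
    i <- findInterval(v, cv, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(cv) - 1L)
    list(i = i, f = (v - cv[i]) / (cv[i + 1] - cv[i]))
  }
  lx <- loc(ax$x, cache$cx)
  ly <- loc(ax$y, cache$cy)
  lz <- loc(ax$z, cache$cz)
  IX <- array(lx$i, d); FX <- array(lx$f, d)
  IY <- array(rep(ly$i, each = d[1]), d)
  FY <- array(rep(ly$f, each = d[1]), d)
  IZ <- array(rep(lz$i, each = d[1] * d[2]), d)
  FZ <- array(rep(lz$f, each = d[1] * d[2]), d)
  out <- vector("list", 3)
  for (k in 1:3) {
    Ac <- cache$A[[k]]
    acc <- array(0, d)
    for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
      wgt <- (if (bx) FX else 1 - FX) * (if (by) FY else 1 - FY) *
        (if (bz) FZ else 1 - FZ)
      lin <- (IX + bx) + dc[1] * ((IY + by - 1L) + dc[2] * (IZ + bz - 1L))
      acc <- acc + wgt * Ac[lin]
    }
    out[[k]] <- acc
  }
  out
}
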