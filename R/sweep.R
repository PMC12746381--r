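# Landmark sweeps and dB/dt-over-E-field ratio studies.
#
# The body is translated along z (coil and compliance volume fixed,
# equivalent to patient-table landmarking); each landmark is solved and the
# myocardial metric set recorded; the worst case per metric is the landmark
# maximizing that metric, ties broken toward smaller |z|.

#' Sweep configuration
#'
#' @param landmark_step landmark spacing along z in m.
#' @param n_landmarks number of landmarks, centered symmetrically about the
#'   isocenter.
#' @param axes character vector of driven axis combinations, subset of
#'   `c("x", "y", "z", "xyz")`.
#' @param slew total slew rate in T/m/s.
#' @param metric_names E-field metrics to tabulate.
#' @param cv_spacing compliance-volume sample spacing in m.
#' @param interp_spacing coarse-lattice spacing for coil vector-potential
#'   evaluation (m); 0 forces exact evaluation.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(landmark_step = 0.05, n_landmarks = 41,
                         axes = "z", slew = 100,
                         metric_names = c("Emax", "E99_9", "E99", "E95"),
                         cv_spacing = 0.01, interp_spacing = 0.008) {
  stopifnot(landmark_step > 0, n_landmarks >= 1, slew > 0)
  axes <- match.arg(tolower(axes), c("x", "y", "z", "xyz"),
                    several.ok = TRUE)
  metric_names <- match.arg(metric_names,
                            c("Emax", "E99_9", "E99", "E95"),
                            several.ok = TRUE)
  structure(list(landmark_step = landmark_step, n_landmarks = n_landmarks,
                 axes = axes, slew = slew, metric_names = metric_names,
                 cv_spacing = cv_spacing, interp_spacing = interp_spacing),
            class = "sweep_config")
}

landmark_offsets <- function(config) {
  (seq_len(config$n_landmarks) - (config$n_landmarks + 1) / 2) *
    config$landmark_step
}

shift_model_z <- function(model, dz) {
  model$origin[3] <- model$origin[3] + dz
  model
}

#' Landmark sweep for one model and source
#'
#' Translates the body along z over the configured landmarks, solves the
#' induced E-field at each, and extracts the myocardial metric set. The
#' worst-case landmark is determined per metric independently.
#'
#' @param model a [voxel_model()] with a `myocardium` mask.
#' @param source coil, [gradient_set()] or ideal field.
#' @param config a [sweep_config()].
#' @param axis driven axis combination for this sweep (defaults to the first
#'   entry of `config$axes`).
#' @param system optional precomputed [fd_system()] for `model`.
#' @param solve_cfg a [solve_config()].
#' @return list with `per_landmark` (data.frame of metrics by landmark),
#'   `worst_case` (named landmark_z per metric) and `worst_value` (named
#'   metric values).
#' @export
run_landmark_sweep <- function(model, source, config = sweep_config(),
                               axis = config$axes[1], system = NULL,
                               solve_cfg = solve_config()) {
  if (is.null(model$masks$myocardium)) stop("model lacks a myocardium mask")
  sys <- if (is.null(system)) fd_system(model) else system
  drive <- drive_spec(slew = config$slew, axes = axis)
  offs <- landmark_offsets(config)
  dax <- driven_axes(source, drive)
  caches <- make_A_caches(dax$sources, model, range(offs),
                          config$interp_spacing)
  rows <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    m2 <- shift_model_z(model, offs[i])
    res <- tryCatch({
      da <- dAdt_from_caches(m2, dax, caches, config$interp_spacing)
      phi <- solve_scalar_potential(m2, da, solve_cfg, system = sys)
      E <- compute_E(phi, da, m2, landmark_z = offs[i], drive = drive)
      ms <- metric_set(E, m2$masks$myocardium)
      data.frame(landmark_z = offs[i], Emax = ms$Emax, E99_9 = ms$E99_9,
                 E99 = ms$E99, E95 = ms$E95, n_voxels = ms$n_voxels,
                 iterations = phi$iterations)
    }, error = function(e) {
      warning("landmark ", offs[i], " skipped: ", conditionMessage(e))
      NULL
    })
    rows[[i]] <- res
  }
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0) stop("all landmarks failed")
  worst <- sapply(config$metric_names, function(mn) {
    best <- max(per[[mn]])
    cand <- per$landmark_z[per[[mn]] == best]
    cand[which.min(abs(cand))]
  })
  wval <- sapply(config$metric_names, function(mn) max(per[[mn]]))
  list(per_landmark = per, worst_case = worst, worst_value = wval)
}

#' dB/dt-over-E-field conversion ratio
#'
#' @param peak_dBdt peak dB/dt over the compliance volume in T/s.
#' @param E_value myocardial E-field metric in V/m (> 0).
#' @return ratio in (T/s) (V/m)^-1.
#' @examples
#' compute_ratio(100, 10)  # the historical homogeneous-ellipsoid value, 10
#' @export
compute_ratio <- function(peak_dBdt, E_value) {
  if (any(E_value <= 0)) stop("E_value must be positive")
  peak_dBdt / E_value
}

#' Run a ratio study
#'
#' Cartesian product of body models, gradient coils and axis combinations:
#' for each combination a landmark sweep is run and the worst-case ratio per
#' metric is recorded. Individual failures are logged in the provenance and
#' the study continues. The finite-difference system is built once per model
#' and reused across coils, axes and landmarks.
#'
#' @param models named list of [voxel_model()]s.
#' @param coils list of [gradient_set()]s (all axes available) and/or
#'   [coil_model()]s (only their own axis is driven).
#' @param config a [sweep_config()].
#' @param solve_cfg a [solve_config()].
#' @param seed integer recorded in the provenance (the study itself is
#'   deterministic given models and coils).
#' @return object of class `ratio_table`: `records` data.frame with columns
#'   model_id, coil_id, axis, landmark_z, metric, E_value, peak_dBdt, ratio;
#'   `provenance` list.
#' @export
run_study <- function(models, coils, config = sweep_config(),
                      solve_cfg = solve_config(), seed = NULL) {
  if (is.null(names(models)))
    names(models) <- sprintf("model%02d", seq_along(models))
  recs <- list()
  failures <- character()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    sys <- fd_system(model)
    for (ci in seq_along(coils)) {
      coil <- coils[[ci]]
      cname <- if (!is.null(coil$name)) coil$name else paste0("coil", ci)
      axes <- if (inherits(coil, "gradient_set")) config$axes
              else intersect(config$axes, coil$axis)
      for (ax in axes) {
        key <- paste(names(models)[mi], cname, ax, sep = "/")
        res <- tryCatch({
          drive <- drive_spec(slew = config$slew, axes = ax)
          peak <- compliance_peak_dBdt(
            coil, drive, compliance_volume(spacing = config$cv_spacing))
          sw <- run_landmark_sweep(model, coil, config, axis = ax,
                                   system = sys, solve_cfg = solve_cfg)
          do.call(rbind, lapply(config$metric_names, function(mn) {
            ev <- sw$worst_value[[mn]]
            data.frame(model_id = names(models)[mi], coil_id = cname,
                       axis = ax, landmark_z = sw$worst_case[[mn]],
                       metric = mn, E_value = ev, peak_dBdt = peak,
                       ratio = compute_ratio(peak, ev),
                       stringsAsFactors = FALSE)
          }))
        }, error = function(e) {
          failures <<- c(failures, paste0(key, ": ", conditionMessage(e)))
          NULL
        })
        recs[[key]] <- res
      }
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records))
    stop("study produced no records (", length(failures), " failures; ",
         "check that the requested axes match the supplied coils)")
  rownames(records) <- NULL
  if (!is.null(records) &&
      anyDuplicated(records[c("model_id", "coil_id", "axis", "metric")]))
    stop("duplicate (model, coil, axis, metric) keys in ratio table")
  structure(list(records = records,
                 provenance = list(config = unclass(config),
                                   solve_config = unclass(solve_cfg),
                                   seed = seed, failures = failures)),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("ratio_table:", nrow(x$records), "records,",
      length(x$provenance$failures), "failures\n")
  invisible(x)
}

#' Aggregate a ratio distribution
#'
#' Worst case (minimum) and nearest-rank lower percentiles of the
#' dB/dt-over-E ratios for one metric, each (model, coil, axis) worst-case
#' contributing one sample.
#'
#' @param table a [run_study()] result.
#' @param metric_name one of `"Emax"`, `"E99_9"`, `"E99"`, `"E95"`.
#' @param probs lower-tail percentiles (percent).
#' @param breaks histogram bin specification.
#' @return list with `worst_case`, `percentiles`, `histogram`, `n`.
#' @export
aggregate_ratios <- function(table, metric_name,
                             probs = c(0.1, 1, 10), breaks = 20) {
  stopifnot(inherits(table, "ratio_table"))
  r <- table$records$ratio[table$records$metric == metric_name]
  if (length(r) == 0) stop("no records for metric ", metric_name)
  x <- sort(r)
  pct <- sapply(probs, function(p) x[max(1, ceiling(p * length(x) / 100))])
  names(pct) <- paste0("p", probs)
  hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(worst_case = x[1], percentiles = pct,
       histogram = data.frame(bin_lo = head(hh$breaks, -1),
                              bin_hi = tail(hh$breaks, -1),
                              count = hh$counts),
       n = length(x))
}

# mean |B| per unit current over the heart volume at each landmark offset:
# the exhaustive-sweep oracle for worst-case landmark placement
heart_meanB_profile <- function(model, source, offsets, drive = drive_spec(),
                                max_voxels = 2000) {
  mask <- model$masks$heart_total
  if (is.null(mask)) mask <- model$masks$myocardium
  idx <- which(mask)
  if (length(idx) > max_voxels)
    idx <- idx[seq(1, length(idx), length.out = max_voxels)]
  da <- driven_axes(source, drive)
  sapply(offsets, function(off) {
    pts <- voxel_centers(shift_model_z(model, off), idx)
    Btot <- matrix(0, nrow(pts), 3)
    for (i in seq_along(da$sources))
      Btot <- Btot + biot_savart_B(da$sources[[i]], pts)$values *
        drive_scale(da$sources[[i]], da$slews[i])
    mean(sqrt(rowSums(Btot^2)))
  })
}
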