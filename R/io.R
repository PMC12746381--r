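# Plain-text serialization. Ratio tables travel as CSV with a fixed column
# order plus a provenance JSON sidecar; voxel models as a JSON header plus a
# flat integer label file (no binary formats).

ratio_table_columns <- c("model_id", "coil_id", "axis", "landmark_z",
                         "metric", "E_value", "peak_dBdt", "ratio")

#' Write a ratio table
#'
#' @param table a [run_study()] result.
#' @param file CSV path; a `<file>.provenance.json` sidecar is written next
#'   to it.
#' @return `file`, invisibly.
#' @export
write_ratio_table <- function(table, file) {
  stopifnot(inherits(table, "ratio_table"))
  write.csv(table$records[ratio_table_columns], file, row.names = FALSE)
  jsonlite::write_json(table$provenance,
                       paste0(file, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read a ratio table
#'
#' @param file CSV path written by [write_ratio_table()] (the provenance
#'   sidecar is optional).
#' @return a `ratio_table`.
#' @export
read_ratio_table <- function(file) {
  records <- read.csv(file, stringsAsFactors = FALSE)
  missing <- setdiff(ratio_table_columns, names(records))
  if (length(missing))
    stop("ratio table is missing columns: ", paste(missing, collapse = ", "))
  prov_file <- paste0(file, ".provenance.json")
  prov <- if (file.exists(prov_file)) jsonlite::read_json(prov_file)
          else list()
  structure(list(records = records, provenance = prov),
            class = "ratio_table")
}

#' Extract ratio samples for one metric
#'
#' Accepts either a [ratio_table()] CSV from this package or a plain CSV
#' with one column per metric (columns named e.g. `E99`, `Emax`).
#'
#' @param file CSV path.
#' @param metric metric name.
#' @return a [ratio_distribution()].
#' @export
read_ratio_samples <- function(file, metric = "E99") {
  df <- read.csv(file, stringsAsFactors = FALSE)
  samples <- if (all(c("metric", "ratio") %in% names(df))) {
    df$ratio[df$metric == metric]
  } else if (metric %in% names(df)) {
    df[[metric]]
  } else {
    stop("no ratio samples for metric '", metric, "' in ", file)
  }
  ratio_distribution(samples[is.finite(samples)], source = file)
}

#' Write a voxel model as text
#'
#' Writes `<dir>/model.json` (spacing, origin, tissue table, mask names)
#' and flat integer files `labels.txt` / `mask_<name>.txt` in column-major
#' order.
#'
#' @param model a [voxel_model()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_voxel_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(name = model$name, dims = dim(model$labels),
              spacing_mm = model$spacing, origin_m = model$origin,
              tissues = as.data.frame(unclass(model$tissues)),
              masks = names(model$masks))
  jsonlite::write_json(hdr, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(as.character(as.vector(model$labels)),
             file.path(dir, "labels.txt"))
  for (nm in names(model$masks))
    writeLines(as.character(as.integer(as.vector(model$masks[[nm]]))),
               file.path(dir, paste0("mask_", nm, ".txt")))
  invisible(dir)
}

#' Read a voxel model written by [write_voxel_model()]
#'
#' @param dir directory containing `model.json`.
#' @return a [voxel_model()].
#' @export
read_voxel_model <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  d <- as.integer(hdr$dims)
  labels <- array(as.integer(readLines(file.path(dir, "labels.txt"))), d)
  masks <- list()
  for (nm in hdr$masks)
    masks[[nm]] <- array(
      as.integer(readLines(file.path(dir, paste0("mask_", nm, ".txt")))) > 0,
      d)
  tis <- tissue_table(hdr$tissues$label, hdr$tissues$name, hdr$tissues$sigma)
  voxel_model(labels, hdr$spacing_mm, hdr$origin_m, tis, masks,
              name = hdr$name)
}

#' Write a coil model as JSON
#'
#' @param coil a [coil_model()].
#' @param file JSON path.
#' @return `file`, invisibly.
#' @export
write_coil_model <- function(coil, file) {
  stopifnot(inherits(coil, "coil_model"))
  obj <- list(name = coil$name, axis = coil$axis,
              inner_diameter = coil$inner_diameter, length = coil$length,
              loops = lapply(coil$loops, function(lp)
                list(current = lp$current,
                     vertices = unname(lp$vertices))))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a coil model written by [write_coil_model()]
#'
#' @param file JSON path.
#' @return a [coil_model()].
#' @export
read_coil_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  loops <- lapply(seq_len(nrow(obj$loops)), function(i)
    list(current = obj$loops$current[i],
         vertices = obj$loops$vertices[[i]]))
  coil_model(loops, obj$axis, obj$inner_diameter, obj$length,
             name = obj$name, override = TRUE)
}
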