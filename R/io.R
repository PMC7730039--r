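#' Write a mesh with fields as a legacy-ASCII VTK unstructured grid
#'
#' @param mesh an `oh_mesh`.
#' @param path output file (.vtk).
#' @param cell_data named list of per-element vectors (numeric or factor).
#' @param point_data named list of per-node numeric vectors.
#' @param title dataset title line (units are mm, MPa, um/s).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list(),
                      title = "osseoheal fields (mm, MPa, um/s)") {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", title, "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(paste("POINTS", n, "double"))
  wl(paste(format(mesh$nodes$r, digits = 12),
           format(mesh$nodes$z, digits = 12), "0"))
  conn <- mesh_conn(mesh) - 1L
  wl(paste("CELLS", m, 5 * m))
  wl(paste(4L, conn[, 1], conn[, 2], conn[, 3], conn[, 4]))
  wl(paste("CELL_TYPES", m))
  wl(as.character(rep(9L, m)))
  emit <- function(name, x) {
    if (is.factor(x) || is.character(x)) x <- as.integer(as.factor(x))
    x[is.na(x)] <- -1
    wl(paste("SCALARS", name, "double", 1), "LOOKUP_TABLE default")
    wl(format(as.numeric(x), digits = 12))
  }
  if (length(cell_data) > 0) {
    wl(paste("CELL_DATA", m))
    for (nm in names(cell_data)) emit(nm, cell_data[[nm]])
  }
  if (length(point_data) > 0) {
    wl(paste("POINT_DATA", n))
    for (nm in names(point_data)) emit(nm, point_data[[nm]])
  }
  invisible(path)
}

#' Write the daily outputs of a healing run
#'
#' Emits one VTK frame per healing day (phenotype code, stimulus, Young's
#' modulus and concentration on the callus; region codes elsewhere) plus a
#' `daily.csv` summary with one row per day. Re-running produces
#' byte-identical CSVs.
#'
#' @param history an `oh_healing` run.
#' @param outdir output directory (created if missing).
#' @return Tibble of written file paths, invisibly.
#' @export
write_timeseries <- function(history, outdir) {
  stopifnot(inherits(history, "oh_healing"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mesh <- history$mesh
  m <- nrow(mesh$elements)
  phen_code <- function(ph) as.integer(factor(ph, phenotype_levels()))
  files <- character(0)
  for (d in seq_len(history$days)) {
    fld <- history$fields[[d]]
    full_phen <- rep(NA_character_, m)
    full_phen[fld$element] <- as.character(fld$phenotype)
    full_S <- rep(NA_real_, m)
    full_S[fld$element] <- fld$S
    full_E <- history$table$young_modulus[
      match(c(implant = "implant", cortical = "cortical",
              cancellous = "cancellous")[mesh$elements$region],
            history$table$phenotype)]
    full_E[fld$element] <- fld$young_modulus
    f <- file.path(outdir, sprintf("day_%02d.vtk", d))
    write_vtk(mesh, f, cell_data = list(
      phenotype = phen_code(full_phen),
      stimulus = full_S,
      young_modulus = full_E))
    files <- c(files, f)
  }
  csv <- file.path(outdir, "daily.csv")
  utils::write.csv(as.data.frame(history$daily), csv, row.names = FALSE)
  manifest <- file.path(outdir, "run.yaml")
  yaml::write_yaml(list(
    days = history$days, D_mm2_day = history$D,
    smoothing_window = history$N,
    stimulus_constants = history$constants,
    load_um = history$load$top_displacement,
    interface_mode = history$interface$mode), manifest)
  invisible(tibble::tibble(file = c(files, csv, manifest)))
}
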