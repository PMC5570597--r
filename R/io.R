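# Run-directory I/O: VTK legacy structured-points snapshots for visual
# inspection, RDS checkpoints for exact round-trip, YAML/JSON configs.

#' Write a legacy-VTK structured-points snapshot
#'
#' Cell data (e.g. region labels) and point data (e.g. Vm, phi_e) on the
#' structured grid, in ASCII legacy VTK format.
#' @param path output file.
#' @param grid labelled grid.
#' @param cell_data named list of per-cell vectors.
#' @param point_data named list of per-node vectors.
#' @export
write_vtk_image <- function(path, grid, cell_data = list(),
                            point_data = list()) {
  nd <- grid$dim
  dims <- if (nd == 2L) c(grid$ndims, 1L) else grid$ndims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "labelled structured grid snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h)), con)
  fmt <- function(v) paste(format(v, digits = 9, trim = TRUE,
                                  scientific = FALSE), collapse = "\n")
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", prod(grid$dims)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default", fmt(cell_data[[nm]])), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n_nodes(grid)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default", fmt(point_data[[nm]])), con)
    }
  }
  invisible(path)
}

#' Save / load an exact simulation checkpoint
#'
#' The checkpoint stores the full state (Vm, membrane state, phi_e, time)
#' plus hashes of the grid labels and the run configuration, and round-trips
#' bit-exactly.
#' @param path file path (.rds).
#' @param state simulation state.
#' @param grid labelled grid the state lives on.
#' @param config optional configuration list.
#' @export
save_checkpoint <- function(path, state, grid, config = NULL) {
  obj <- list(state = state,
              grid_hash = grid_hash(grid),
              config_hash = if (is.null(config)) NA_character_
                            else config_hash(config),
              config = config)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_grid if given, the stored grid hash is verified.
#' @export
load_checkpoint <- function(path, expect_grid = NULL) {
  obj <- readRDS(path)
  if (!is.null(expect_grid) && !identical(obj$grid_hash, grid_hash(expect_grid)))
    stop("checkpoint was written for a different grid")
  obj
}

hash_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

grid_hash <- function(grid) hash_of(list(grid$dims, grid$spacing, grid$labels))
config_hash <- function(config) hash_of(config)
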