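#' Write a labeled tetrahedral mesh as a legacy VTK unstructured grid
#'
#' ASCII legacy-dialect VTK with the per-element region stored as an
#' integer cell scalar; the region-name dictionary is packed into the
#' title line so the labels survive a round trip. Optional nodal and
#' element fields (e.g. displacements, stresses) are appended as
#' POINT_DATA / CELL_DATA arrays.
#'
#' @param mesh A `labeled_tet_mesh`.
#' @param path Output path (conventionally `.vtk`).
#' @param point_data Optional named list of numeric vectors (length
#'   n_nodes) or matrices (n_nodes x 3 written as VECTORS).
#' @param cell_data Optional named list of per-element vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  lev <- unique(mesh$region)
  writeLines("# vtk DataFile Version 3.0", con)
  writeLines(paste0("spinepinn regions: ", paste(lev, collapse = ",")), con)
  writeLines("ASCII", con)
  writeLines("DATASET UNSTRUCTURED_GRID", con)
  n <- nrow(mesh$nodes)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(apply(format(mesh$nodes, digits = 17, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)

  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines("SCALARS region int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(match(mesh$region, lev) - 1L), con)
  if (!is.null(cell_data)) {
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      writeLines(sprintf("SCALARS %s double 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(v, digits = 17, scientific = TRUE, trim = TRUE), con)
    }
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(format(v, digits = 17, scientific = TRUE,
                                trim = TRUE), 1, paste, collapse = " "), con)
      } else {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(format(v, digits = 17, scientific = TRUE, trim = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk()]
#'
#' Restores nodes, tetrahedra and region labels; the global `top` and
#' `bottom` node sets are reconstructed from the extreme z planes.
#'
#' @param path Path to the `.vtk` file.
#' @return A `labeled_tet_mesh` (without the generating `phantom_spec`).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1]))
    stop("not a legacy VTK file: ", path)
  lev <- NULL
  if (grepl("^spinepinn regions:", lines[2]))
    lev <- strsplit(sub("^spinepinn regions: *", "", lines[2]), ",")[[1]]
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(as.numeric(unlist(strsplit(trimws(
    lines[(ip + 1):(ip + n)]), "\\s+"))), ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cl <- matrix(as.integer(unlist(strsplit(trimws(
    lines[(ic + 1):(ic + m)]), "\\s+"))), ncol = 5L, byrow = TRUE)
  if (any(cl[, 1] != 4L)) stop("non-tetrahedral cell in VTK file")
  tets <- cl[, 2:5, drop = FALSE] + 1L
  ir <- grep("^SCALARS region", lines)[1]
  region_idx <- as.integer(lines[(ir + 2):(ir + 1 + m)]) + 1L
  region <- if (is.null(lev)) as.character(region_idx) else lev[region_idx]
  zr <- range(nodes[, 3])
  ztol <- 1e-9 * max(1, diff(zr))
  structure(list(
    nodes = nodes, tets = tets, region = region,
    region_type = ifelse(grepl("^vertebra", region), "bone", "disc"),
    node_sets = list(bottom = which(abs(nodes[, 3] - zr[1]) <= ztol),
                     top = which(abs(nodes[, 3] - zr[2]) <= ztol)),
    spec = NULL, grid = NULL
  ), class = "labeled_tet_mesh")
}
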