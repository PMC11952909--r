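#' Construct a triangulated surface mesh
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param triangles Integer matrix, m x 3, 1-based vertex indices.
#' @param region Optional per-triangle labels (e.g. owning phantom region).
#' @return An object of class `surface_mesh` with per-triangle outward unit
#'   normals (as oriented by the triangle winding) and a recorded
#'   watertightness flag (every edge shared by exactly two triangles with
#'   consistent orientation).
#' @export
surface_mesh <- function(vertices, triangles, region = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(
    vertices = vertices,
    triangles = triangles,
    normals = triangle_normals(vertices, triangles),
    region = region,
    watertight = is_watertight(triangles)
  ), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, watertight: %s\n",
              nrow(x$vertices), nrow(x$triangles), x$watertight))
  invisible(x)
}

triangle_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) warning("degenerate triangle(s): zero normal retained")
  n / ifelse(len > 0, len, 1)
}

triangle_centroids <- function(vertices, triangles) {
  (vertices[triangles[, 1], , drop = FALSE] +
     vertices[triangles[, 2], , drop = FALSE] +
     vertices[triangles[, 3], , drop = FALSE]) / 3
}

# Watertight: every directed edge appears exactly once with its reverse
# also present (closed, consistently oriented, manifold surface).
is_watertight <- function(triangles) {
  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(edges[, 1], edges[, 2])
  rkey <- paste(edges[, 2], edges[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Read a stereolithography (STL) surface file
#'
#' Supports both ASCII and binary STL; the variant is auto-detected.
#' Coincident vertices (exact coordinate matches after the float32 STL
#' representation) are merged so the result can be checked for
#' watertightness.
#'
#' @param path Path to an `.stl` file.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  head_raw <- readBin(con, "raw", n = 80L)
  close(con)
  is_ascii <- length(head_raw) >= 5L &&
    identical(rawToChar(head_raw[1:5]), "solid") &&
    stl_looks_ascii(path)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

# Binary STL files may also start with "solid"; confirm by looking for a
# "facet" keyword in the first few lines of text.
stl_looks_ascii <- function(path) {
  lines <- tryCatch(
    suppressWarnings(readLines(path, n = 10L, warn = FALSE)),
    error = function(e) character()
  )
  any(grepl("facet", lines, fixed = TRUE)) ||
    (length(lines) > 0 && all(validEnc(lines)) && length(lines) <= 2)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  verts <- list()
  nv <- 0L
  in_loop <- FALSE
  loop_verts <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "solid") || startsWith(ln, "endsolid") ||
        startsWith(ln, "facet") || startsWith(ln, "endfacet"))
      next
    if (startsWith(ln, "outer loop")) { in_loop <- TRUE; loop_verts <- 0L; next }
    if (startsWith(ln, "endloop")) {
      if (loop_verts != 3L)
        stop(sprintf("malformed STL at line %d: loop with %d vertices", i, loop_verts))
      in_loop <- FALSE
      next
    }
    if (startsWith(ln, "vertex")) {
      if (!in_loop) stop(sprintf("malformed STL at line %d: vertex outside loop", i))
      xyz <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]][2:4]))
      if (any(is.na(xyz)))
        stop(sprintf("malformed STL at line %d: unparsable vertex", i))
      nv <- nv + 1L
      verts[[nv]] <- xyz
      loop_verts <- loop_verts + 1L
      next
    }
    stop(sprintf("malformed STL at line %d: unexpected token '%s'",
                 i, strsplit(ln, "\\s+")[[1]][1]))
  }
  if (nv == 0L || nv %% 3L != 0L)
    stop("malformed STL: vertex count ", nv, " is not a positive multiple of 3")
  stl_from_soup(do.call(rbind, verts))
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (is.na(ntri) || ntri < 0 || expected > sz)
    stop(sprintf("malformed binary STL: header at byte 80 declares %s triangles but file has %d bytes",
                 ntri, sz))
  soup <- matrix(NA_real_, nrow = 3L * ntri, ncol = 3L)
  for (t in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(vals) < 12L)
      stop(sprintf("malformed binary STL: truncated record at byte %d",
                   84 + 50 * (t - 1)))
    soup[(3 * t - 2):(3 * t), ] <- matrix(vals[4:12], nrow = 3, byrow = TRUE)
    readBin(con, "raw", n = 2L) # attribute byte count
  }
  stl_from_soup(soup)
}

# Merge the triangle soup's coincident vertices into an indexed mesh.
stl_from_soup <- function(soup) {
  key <- paste(soup[, 1], soup[, 2], soup[, 3])
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  vertices <- soup[uniq, , drop = FALSE]
  triangles <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(vertices, triangles)
}

#' Write a surface mesh as STL
#'
#' @param surface A [surface_mesh()].
#' @param path Output path.
#' @param binary Write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path, binary = TRUE) {
  stopifnot(inherits(surface, "surface_mesh"))
  v <- surface$vertices
  tri <- surface$triangles
  n <- surface$normals
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "binary STL written by spinepinn"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
    for (t in seq_len(nrow(tri))) {
      rec <- c(n[t, ], t(v[tri[t, ], ]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid spinepinn", con)
    for (t in seq_len(nrow(tri))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e", n[t, 1], n[t, 2], n[t, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[tri[t, j], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid spinepinn", con)
  }
  invisible(path)
}
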