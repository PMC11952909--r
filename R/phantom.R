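#' Specify a synthetic lumbar-spine phantom
#'
#' The phantom is a stack of vertebral-body and intervertebral-disc regions
#' along the cranio-caudal (z) axis: `n_vertebrae` bone regions alternating
#' with `n_vertebrae - 1` disc regions, meshed as one conforming tetrahedral
#' grid so that bone and disc share interface nodes exactly (the tied-contact
#' idealisation). The cross-section is a cylinder (default) or a box;
#' anatomical realism is deliberately not attempted — the phantom exists to
#' exercise the inverse-identification method.
#'
#' @param n_vertebrae Number of vertebral regions (default 5, an L1-L5
#'   stack).
#' @param vertebra_height,disc_height Region heights in mm.
#' @param cross_section `"cylinder"` or `"box"`.
#' @param radius Cylinder radius in mm (cylinder cross-section).
#' @param half_width Length-2 vector of box half-widths in mm (box
#'   cross-section).
#' @param mesh_resolution Target element edge length in mm.
#' @param seed Integer seed recorded with the spec (generation itself is
#'   deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_vertebrae = 5L, vertebra_height = 28,
                         disc_height = 10, cross_section = c("cylinder", "box"),
                         radius = 20, half_width = c(20, 20),
                         mesh_resolution = 7, seed = 1L) {
  cross_section <- match.arg(cross_section)
  if (n_vertebrae < 1L) stop("n_vertebrae must be >= 1")
  if (vertebra_height <= 0 || disc_height <= 0)
    stop("region heights must be strictly positive")
  if (mesh_resolution <= 0) stop("mesh_resolution must be positive")
  if (cross_section == "cylinder" && radius <= 0) stop("radius must be positive")
  if (cross_section == "box" && any(half_width <= 0))
    stop("half widths must be positive")
  structure(list(
    n_vertebrae = as.integer(n_vertebrae),
    vertebra_height = vertebra_height, disc_height = disc_height,
    cross_section = cross_section, radius = radius,
    half_width = half_width, mesh_resolution = mesh_resolution,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Region names for the stack, bottom to top: vertebra_1, disc_1, ...
phantom_region_names <- function(n_vertebrae) {
  if (n_vertebrae == 1L) return("vertebra_1")
  out <- character(2L * n_vertebrae - 1L)
  out[seq(1L, length(out), by = 2L)] <- paste0("vertebra_", seq_len(n_vertebrae))
  out[seq(2L, length(out), by = 2L)] <- paste0("disc_", seq_len(n_vertebrae - 1L))
  out
}

#' Build a labeled tetrahedral phantom mesh
#'
#' Generates the structured conforming tetrahedral mesh of the stack
#' described by a [phantom_spec()]. Each hexahedral grid cell is split into
#' five tetrahedra with the split parity alternating between neighbouring
#' cells, which keeps the mesh conforming and mirror-symmetric about the
#' stack axis (so volume-averaged shear responses vanish under axial
#' loading). A cylindrical cross-section is obtained by the smooth
#' square-to-disk mapping of the unit square.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `labeled_tet_mesh` with fields `nodes` (n x 3,
#'   mm), `tets` (m x 4, 1-based, positively oriented), `region` (character
#'   per tet), `region_type` (`"bone"`/`"disc"` per tet), `node_sets`
#'   (named list: `top`, `bottom`, and `<region>_lower` / `<region>_upper`
#'   interface planes) and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  res <- spec$mesh_resolution
  if (spec$cross_section == "cylinder") {
    wx <- wy <- 2 * spec$radius
  } else {
    wx <- 2 * spec$half_width[1]; wy <- 2 * spec$half_width[2]
  }
  even_up <- function(n) if (n %% 2L == 1L) n + 1L else n
  nx <- even_up(max(2L, as.integer(ceiling(wx / res))))
  ny <- even_up(max(2L, as.integer(ceiling(wy / res))))

  regions <- phantom_region_names(spec$n_vertebrae)
  heights <- ifelse(grepl("^vertebra", regions),
                    spec$vertebra_height, spec$disc_height)
  layers_per_region <- pmax(1L, as.integer(round(heights / res)))
  nz <- sum(layers_per_region)
  # z coordinate of every node plane, uniform within each region
  z_planes <- 0
  for (r in seq_along(regions)) {
    h <- heights[r]; nl <- layers_per_region[r]
    z_planes <- c(z_planes, z_planes[length(z_planes)] + h / nl * seq_len(nl))
  }
  region_of_layer <- rep(seq_along(regions), layers_per_region)

  # nodes
  u <- seq(-1, 1, length.out = nx + 1L)
  v <- seq(-1, 1, length.out = ny + 1L)
  g2 <- expand.grid(u = u, v = v)
  if (spec$cross_section == "cylinder") {
    x2 <- spec$radius * g2$u * sqrt(1 - g2$v^2 / 2)
    y2 <- spec$radius * g2$v * sqrt(1 - g2$u^2 / 2)
  } else {
    x2 <- spec$half_width[1] * g2$u
    y2 <- spec$half_width[2] * g2$v
  }
  npl <- (nx + 1L) * (ny + 1L)
  nodes <- cbind(rep(x2, nz + 1L), rep(y2, nz + 1L),
                 rep(z_planes, each = npl))

  nid <- function(i, j, k) i + (nx + 1L) * j + npl * k + 1L

  # cells -> 5 tets, parity-alternating split
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  c000 <- nid(cells$i,      cells$j,      cells$k)
  c100 <- nid(cells$i + 1L, cells$j,      cells$k)
  c010 <- nid(cells$i,      cells$j + 1L, cells$k)
  c110 <- nid(cells$i + 1L, cells$j + 1L, cells$k)
  c001 <- nid(cells$i,      cells$j,      cells$k + 1L)
  c101 <- nid(cells$i + 1L, cells$j,      cells$k + 1L)
  c011 <- nid(cells$i,      cells$j + 1L, cells$k + 1L)
  c111 <- nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  par0 <- (cells$i + cells$j + cells$k) %% 2L == 0L

  tet_block <- function(a, b, c, d) cbind(a, b, c, d)
  tets_even <- rbind(
    tet_block(c000[par0], c100[par0], c010[par0], c001[par0]),
    tet_block(c110[par0], c010[par0], c100[par0], c111[par0]),
    tet_block(c101[par0], c001[par0], c100[par0], c111[par0]),
    tet_block(c011[par0], c001[par0], c111[par0], c010[par0]),
    tet_block(c100[par0], c010[par0], c001[par0], c111[par0])
  )
  p1 <- !par0
  tets_odd <- rbind(
    tet_block(c100[p1], c000[p1], c110[p1], c101[p1]),
    tet_block(c010[p1], c000[p1], c011[p1], c110[p1]),
    tet_block(c001[p1], c000[p1], c101[p1], c011[p1]),
    tet_block(c111[p1], c110[p1], c011[p1], c101[p1]),
    tet_block(c000[p1], c110[p1], c101[p1], c011[p1])
  )
  tets <- rbind(tets_even, tets_odd)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  region_idx <- c(rep(region_of_layer[cells$k[par0] + 1L], 5L),
                  rep(region_of_layer[cells$k[p1] + 1L], 5L))

  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]; tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0))
    stop("mesh_resolution too coarse: degenerate (zero-volume) tetrahedra")
  region <- regions[region_idx]
  if (!all(regions %in% region))
    stop("mesh_resolution too coarse: some region received no tetrahedra")

  # node sets: global top/bottom plus per-region lower/upper planes
  plane_nodes <- function(k) as.integer(nid(rep(0:nx, ny + 1L),
                                            rep(0:ny, each = nx + 1L), k))
  node_sets <- list(bottom = plane_nodes(0L), top = plane_nodes(nz))
  kcum <- cumsum(c(0L, layers_per_region))
  for (r in seq_along(regions)) {
    node_sets[[paste0(regions[r], "_lower")]] <- plane_nodes(kcum[r])
    node_sets[[paste0(regions[r], "_upper")]] <- plane_nodes(kcum[r + 1L])
  }

  structure(list(
    nodes = nodes, tets = tets, region = region,
    region_type = ifelse(grepl("^vertebra", region), "bone", "disc"),
    node_sets = node_sets, spec = spec,
    grid = list(nx = nx, ny = ny, nz = nz, z_planes = z_planes)
  ), class = "labeled_tet_mesh")
}

#' @export
print.labeled_tet_mesh <- function(x, ...) {
  cat(sprintf("labeled_tet_mesh: %d nodes, %d tets, regions: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes n x 3 coordinate matrix.
#' @param tets m x 4 index matrix.
#' @return Numeric vector of signed volumes (same cubic unit as `nodes`).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
     b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
     b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

#' Analytic volume of the solid a phantom mesh discretises
#'
#' The generated mesh is a prism over its piecewise-linear cross-section
#' polygon, so the exact volume of the discretised solid is the shoelace
#' area of the boundary polygon times the stack height. The sum of the
#' tetrahedral volumes must reproduce this to near machine precision.
#'
#' @param mesh A [build_phantom()] result.
#' @return Volume in mm^3.
#' @export
phantom_prism_volume <- function(mesh) {
  g <- mesh$grid
  bottom <- mesh$node_sets$bottom
  xy <- mesh$nodes[bottom, 1:2, drop = FALSE]
  # boundary nodes of the (nx+1) x (ny+1) plane, counter-clockwise
  nx <- g$nx; ny <- g$ny
  at <- function(i, j) (j * (nx + 1L) + i + 1L)
  ring <- c(at(0:nx, 0L), at(nx, 1:ny), at((nx - 1L):0, ny), at(0L, (ny - 1L):1))
  p <- xy[ring, , drop = FALSE]
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  area <- abs(sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2)
  area * max(g$z_planes)
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Boundary faces are the triangles that belong to exactly one tetrahedron,
#' oriented so their normals point away from the owning element.
#'
#' @param mesh A `labeled_tet_mesh`.
#' @return A [surface_mesh()] whose `region` field records the owning region
#'   of each boundary triangle.
#' @export
extract_surface <- function(mesh) {
  tets <- mesh$tets
  faces_of <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
                    tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  owner <- rep(seq_len(nrow(tets)), 4L)
  opp <- c(tets[, 4], tets[, 3], tets[, 1], tets[, 2])
  s1 <- pmin(faces_of[, 1], faces_of[, 2], faces_of[, 3])
  s3 <- pmax(faces_of[, 1], faces_of[, 2], faces_of[, 3])
  s2 <- faces_of[, 1] + faces_of[, 2] + faces_of[, 3] - s1 - s3
  nn <- as.numeric(nrow(mesh$nodes)) + 1
  skey <- s1 + nn * (s2 + nn * s3)
  on_boundary <- !(duplicated(skey) | duplicated(skey, fromLast = TRUE))
  tri <- faces_of[on_boundary, , drop = FALSE]
  opp <- opp[on_boundary]
  owner <- owner[on_boundary]
  # orient outward: normal must point away from the opposite node
  a <- mesh$nodes[tri[, 1], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2], , drop = FALSE] - a
  e2 <- mesh$nodes[tri[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  toward <- mesh$nodes[opp, , drop = FALSE] - a
  wrong <- rowSums(n * toward) > 0
  tri[wrong, 2:3] <- tri[wrong, 3:2]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  surface_mesh(mesh$nodes[used, , drop = FALSE],
               matrix(remap[tri], ncol = 3L),
               region = mesh$region[owner])
}

#' Annotate upper and lower endplate triangles of a surface
#'
#' A triangle belongs to the upper endplate when its outward normal makes an
#' angle of at most `max_angle_deg` with `+axis` and its centroid's
#' coordinate along `axis` lies inside the upper distance band; the lower
#' endplate is defined analogously with `-axis`. The selection is a pure
#' per-triangle predicate, hence idempotent and independent of triangle
#' order. When `distance_band` is `NULL`, the band defaults to the top
#' (respectively bottom) 15% of the surface's extent along `axis`. A
#' triangle passing both predicates (possible only for very thin surfaces)
#' is assigned to the side whose axis direction is closer to its normal,
#' keeping the sets disjoint.
#'
#' @param surface A [surface_mesh()].
#' @param max_angle_deg Maximum normal-to-axis angle in degrees, in (0, 90).
#' @param distance_band Optional length-2 numeric `(min, max)` in mm: the
#'   admissible centroid coordinate along `axis`, applied to both sides.
#' @param axis Unit stack-axis vector (default +z).
#' @return List with integer triangle-index vectors `upper` and `lower`.
#'   Empty selections produce a warning, not an error.
#' @export
annotate_endplates <- function(surface, max_angle_deg = 30,
                               distance_band = NULL, axis = c(0, 0, 1)) {
  stopifnot(inherits(surface, "surface_mesh"))
  if (max_angle_deg <= 0 || max_angle_deg >= 90)
    stop("max_angle_deg must be strictly between 0 and 90")
  axis <- axis / sqrt(sum(axis^2))
  cen <- triangle_centroids(surface$vertices, surface$triangles)
  d <- as.vector(cen %*% axis)
  cosang <- as.vector(surface$normals %*% axis)
  cosmax <- cos(max_angle_deg * pi / 180)
  if (is.null(distance_band)) {
    ext <- range(d)
    span <- diff(ext)
    band_up <- c(ext[2] - 0.15 * span, ext[2])
    band_lo <- c(ext[1], ext[1] + 0.15 * span)
  } else {
    band_up <- band_lo <- sort(distance_band)
  }
  up <- which(cosang >= cosmax & d >= band_up[1] & d <= band_up[2])
  lo <- which(-cosang >= cosmax & d >= band_lo[1] & d <= band_lo[2])
  both <- intersect(up, lo)
  if (length(both)) {
    to_lower <- both[-cosang[both] > cosang[both]]
    up <- setdiff(up, to_lower)
    lo <- setdiff(lo, setdiff(both, to_lower))
  }
  if (length(up) == 0L) warning("upper endplate selection is empty")
  if (length(lo) == 0L) warning("lower endplate selection is empty")
  list(upper = up, lower = lo)
}

# Randomly renumber nodes and reorder tets; used to verify that extracted
# response features are invariant under mesh relabeling.
permute_mesh <- function(mesh, seed = 1L) {
  set.seed(seed)
  np <- sample(nrow(mesh$nodes))
  inv <- integer(length(np)); inv[np] <- seq_along(np)
  ep <- sample(nrow(mesh$tets))
  out <- mesh
  out$nodes <- mesh$nodes[np, , drop = FALSE]
  out$tets <- matrix(inv[mesh$tets[ep, ]], ncol = 4L)
  out$region <- mesh$region[ep]
  out$region_type <- mesh$region_type[ep]
  out$node_sets <- lapply(mesh$node_sets, function(s) sort(inv[s]))
  out
}
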