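#' Triangulated surface meshes
#'
#' A `surface_mesh` is the spatial domain for all per-vertex maps in this
#' package: a list with vertex coordinates in mm, a triangle index matrix,
#' per-vertex adjacency, barycentric vertex areas (mm^2) and a discrete
#' signed curvature (angle deficit per unit area, mm^-2 scaled to mm^-1 by
#' the local edge scale is deliberately avoided; the curvature enters the
#' analysis only through linear regression, so its absolute scale is
#' irrelevant).
#'
#' @param kind Either `"icosphere"` (closed sphere obtained by subdividing
#'   a regular icosahedron) or `"planar_patch"` (regular triangulated grid
#'   with open boundary).
#' @param resolution Non-negative integer. For the icosphere, the number of
#'   4-fold subdivision passes (resolution 0 is the icosahedron itself:
#'   12 vertices, 20 triangles). For the planar patch, the grid has
#'   `resolution + 2` vertices per side.
#' @param radius Sphere radius in mm (icosphere only).
#' @param spacing Grid spacing in mm (planar patch only).
#' @return An object of class `surface_mesh` with fields `vertices`
#'   (n x 3 matrix, mm), `triangles` (m x 3 integer matrix, 1-based),
#'   `neighbors` (list of integer vectors), `vertex_area` (mm^2),
#'   `curvature` (signed angle-deficit curvature), `is_boundary` (logical),
#'   and `closed` (logical scalar).
#' @examples
#' m <- build_mesh("icosphere", 1)
#' nrow(m$vertices)  # 42
#' @export
build_mesh <- function(kind = c("icosphere", "planar_patch"), resolution,
                       radius = 10, spacing = 1) {
  kind <- match.arg(kind)
  if (length(resolution) != 1L || is.na(resolution) || resolution < 0 ||
      resolution != round(resolution)) {
    stop("`resolution` must be a single non-negative integer", call. = FALSE)
  }
  resolution <- as.integer(resolution)
  if (kind == "icosphere") {
    geom <- icosphere_geometry(resolution, radius)
  } else {
    geom <- planar_patch_geometry(resolution, spacing)
  }
  finish_mesh(geom$vertices, geom$triangles)
}

# 12-vertex icosahedron, subdivided `resolution` times, projected to a sphere
icosphere_geometry <- function(resolution, radius) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  v <- v / sqrt(rowSums(v^2))
  for (i in seq_len(resolution)) {
    n_v <- nrow(v)
    # midpoint cache keyed on the ordered vertex pair
    key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    e1 <- key(tri[, 1], tri[, 2])
    e2 <- key(tri[, 2], tri[, 3])
    e3 <- key(tri[, 3], tri[, 1])
    all_keys <- unique(c(e1, e2, e3))
    idx <- stats::setNames(seq_along(all_keys) + n_v, all_keys)
    pair <- do.call(rbind, strsplit(all_keys, "_", fixed = TRUE))
    a <- as.integer(pair[, 1]); b <- as.integer(pair[, 2])
    mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    m1 <- idx[e1]; m2 <- idx[e2]; m3 <- idx[e3]
    tri <- rbind(
      cbind(tri[, 1], m1, m3),
      cbind(tri[, 2], m2, m1),
      cbind(tri[, 3], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  list(vertices = v * radius, triangles = tri)
}

planar_patch_geometry <- function(resolution, spacing) {
  n_side <- resolution + 2L
  g <- expand.grid(x = seq_len(n_side) - 1L, y = seq_len(n_side) - 1L)
  v <- cbind(g$x * spacing, g$y * spacing, 0)
  id <- function(ix, iy) (iy - 1L) * n_side + ix
  tris <- vector("list", (n_side - 1L)^2 * 2L)
  k <- 0L
  for (iy in seq_len(n_side - 1L)) {
    for (ix in seq_len(n_side - 1L)) {
      k <- k + 1L
      tris[[k]] <- c(id(ix, iy), id(ix + 1L, iy), id(ix + 1L, iy + 1L))
      k <- k + 1L
      tris[[k]] <- c(id(ix, iy), id(ix + 1L, iy + 1L), id(ix, iy + 1L))
    }
  }
  list(vertices = v, triangles = do.call(rbind, tris))
}

# derive adjacency, areas, curvature and boundary flags; validate invariants
finish_mesh <- function(vertices, triangles) {
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  n <- nrow(vertices)
  edges <- mesh_edge_table(triangles)
  nb <- vector("list", n)
  both <- rbind(edges[, 1:2], edges[, 2:1])
  ord <- order(both[, 1], both[, 2])
  both <- both[ord, , drop = FALSE]
  split_idx <- split(both[, 2], both[, 1])
  nb[as.integer(names(split_idx))] <- lapply(split_idx, as.integer)

  tri_area <- triangle_areas(vertices, triangles)
  va <- numeric(n)
  for (j in 1:3) {
    va <- va + tapply_add(tri_area / 3, triangles[, j], n)
  }

  edge_tri_count <- edges[, 3]
  boundary_edges <- edges[edge_tri_count == 1L, 1:2, drop = FALSE]
  is_boundary <- rep(FALSE, n)
  is_boundary[unique(as.vector(boundary_edges))] <- TRUE
  closed <- nrow(boundary_edges) == 0L

  curv <- angle_deficit_curvature(vertices, triangles, va, is_boundary)

  mesh <- structure(
    list(vertices = vertices, triangles = triangles, neighbors = nb,
         vertex_area = va, curvature = curv, is_boundary = is_boundary,
         closed = closed),
    class = "surface_mesh"
  )
  validate_mesh(mesh)
  mesh
}

# unique undirected edges with incident-triangle counts
mesh_edge_table <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  uniq <- !duplicated(key)
  out <- cbind(e[uniq, , drop = FALSE], as.integer(tab[key[uniq]]))
  colnames(out) <- c("v1", "v2", "n_tri")
  out
}

#' Edge list of a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Integer matrix with columns `v1`, `v2` (v1 < v2) and `n_tri`,
#'   the number of incident triangles (1 on an open boundary, 2 inside).
#' @export
mesh_edges <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mesh_edge_table(mesh$triangles)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- tapply(values, index, sum)
  out[as.integer(names(agg))] <- agg
  out
}

# Discrete Gaussian curvature via angle deficit over barycentric area.
# Interior: (2*pi - sum of incident angles) / area; boundary vertices of an
# open patch use (pi - sum)/area so a flat sheet comes out exactly zero.
angle_deficit_curvature <- function(vertices, triangles, vertex_area,
                                    is_boundary) {
  n <- nrow(vertices)
  angle_sum <- numeric(n)
  for (j in 1:3) {
    i0 <- triangles[, j]
    i1 <- triangles[, (j %% 3) + 1]
    i2 <- triangles[, ((j + 1) %% 3) + 1]
    u <- vertices[i1, , drop = FALSE] - vertices[i0, , drop = FALSE]
    v <- vertices[i2, , drop = FALSE] - vertices[i0, , drop = FALSE]
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    angle_sum <- angle_sum + tapply_add(acos(cosang), i0, n)
  }
  full <- ifelse(is_boundary, pi, 2 * pi)
  (full - angle_sum) / vertex_area
}

#' Validate surface-mesh invariants
#'
#' Checks triangle index validity, adjacency symmetry, strictly positive
#' vertex areas, connectivity and absence of duplicate triangles. Called by
#' [build_mesh()]; exported so user-supplied meshes can be checked too.
#'
#' @param mesh A `surface_mesh`.
#' @return The mesh, invisibly; stops on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  tri <- mesh$triangles
  if (any(tri < 1L) || any(tri > n)) {
    stop("triangle indices out of range", call. = FALSE)
  }
  key <- apply(tri, 1, function(r) paste(sort(r), collapse = "_"))
  if (anyDuplicated(key)) stop("duplicate triangles", call. = FALSE)
  if (any(mesh$vertex_area <= 0)) {
    stop("vertex areas must be strictly positive", call. = FALSE)
  }
  for (i in seq_len(n)) {
    for (j in mesh$neighbors[[i]]) {
      if (!(i %in% mesh$neighbors[[j]])) {
        stop("adjacency not symmetric", call. = FALSE)
      }
    }
  }
  # connectivity by breadth-first search
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    nxt <- mesh$neighbors[[cur]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  if (!all(seen)) stop("mesh is not connected", call. = FALSE)
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "surface_mesh: %d vertices, %d triangles (%s)\n",
    nrow(x$vertices), nrow(x$triangles),
    if (x$closed) "closed" else "open boundary"
  ))
  invisible(x)
}

mean_edge_length <- function(mesh) {
  e <- mesh_edge_table(mesh$triangles)
  d <- mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
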