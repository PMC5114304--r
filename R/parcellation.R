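#' AUC threshold of a cortical value distribution
#'
#' The value at which the cumulative histogram mass between the 3rd and
#' 97th percentiles reaches `pct` percent of the mass in that range, i.e.
#' the pct-quantile of the distribution truncated to [p3, p97] (with the
#' percentile anchors included as range endpoints, so pct = 0 returns p3
#' and pct = 100 returns p97 exactly).
#'
#' @param values Per-vertex numeric vector.
#' @param pct Percentage of the truncated cumulative mass, in [0, 100].
#' @return Threshold in the units of `values`.
#' @export
auc_threshold <- function(values, pct) {
  if (length(pct) != 1L || is.na(pct) || pct < 0 || pct > 100) {
    stop("`pct` must lie in [0, 100]", call. = FALSE)
  }
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) {
    stop("degenerate distribution", call. = FALSE)
  }
  q <- stats::quantile(v, c(0.03, 0.97), names = FALSE, type = 7)
  vt <- v[v > q[1] & v < q[2]]
  unname(stats::quantile(c(q[1], vt, q[2]), pct / 100, names = FALSE,
                         type = 7))
}

#' Threshold coverage profile of a region
#'
#' For each AUC percentage, the fraction of ROI vertices whose value is
#' greater than or equal to the corresponding global AUC threshold. Maps
#' should be oriented to increase with myelination before calling (use
#' [reciprocal_map()] to turn T2*(w) into R2*(w)).
#'
#' @param map Per-vertex numeric vector (thresholds come from its global
#'   distribution).
#' @param atlas An `roi_atlas`.
#' @param roi Region label or name.
#' @param pcts AUC percentages, typically 60--90.
#' @return data.frame with columns `pct`, `threshold`, `coverage`
#'   (percent of ROI vertices).
#' @export
coverage_profile <- function(map, atlas, roi, pcts = seq(60, 90, by = 5)) {
  idx <- roi_vertices(atlas, roi)
  vals <- map[idx]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("region empty after exclusion", call. = FALSE)
  thr <- vapply(pcts, function(p) auc_threshold(map, p), numeric(1))
  cov <- vapply(thr, function(t) 100 * mean(vals >= t), numeric(1))
  data.frame(pct = pcts, threshold = thr, coverage = cov)
}

#' Binarize a map and extract its threshold contour
#'
#' The parcellation mask holds vertices with value greater than or equal
#' to the threshold (excluded/unfittable vertices are `FALSE`); the
#' contour is the set of mesh edges whose endpoints straddle the mask. On
#' a closed mesh every straddling edge lies in exactly two mixed-label
#' triangles, so the contour forms closed loops (see
#' [contour_is_closed()]).
#'
#' @param mesh A `surface_mesh`.
#' @param map Per-vertex numeric vector.
#' @param threshold Threshold value.
#' @param source Optional `(parameter, pct)` annotation stored on the
#'   parcellation.
#' @return List with `parcellation` (a `binary_parcellation`: `mask`,
#'   `source`) and `contour` (edge matrix with columns v1, v2).
#' @export
binarize_and_contour <- function(mesh, map, threshold, source = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mask <- is.finite(map) & map >= threshold
  e <- mesh_edges(mesh)
  straddle <- mask[e[, 1]] != mask[e[, 2]]
  contour <- e[straddle, c(1, 2), drop = FALSE]
  parc <- structure(list(mask = mask, source = source),
                    class = "binary_parcellation")
  list(parcellation = parc, contour = contour)
}

#' Check that a contour forms closed loops
#'
#' On a closed mesh, each contour (straddling) edge must be incident to
#' exactly two triangles of mixed mask labels; the adjacency of straddling
#' edges through those triangles is then 2-regular, i.e. a disjoint union
#' of cycles.
#'
#' @param mesh A closed `surface_mesh`.
#' @param mask Per-vertex logical mask.
#' @return `TRUE` if every straddling edge lies in exactly two
#'   mixed-label triangles.
#' @export
contour_is_closed <- function(mesh, mask) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tri <- mesh$triangles
  mixed <- (mask[tri[, 1]] + mask[tri[, 2]] + mask[tri[, 3]]) %in% c(1L, 2L)
  edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  tab <- table(unlist(lapply(which(mixed), function(t) {
    v <- tri[t, ]
    s <- mask[v]
    k <- c(edge_key(v[1], v[2]), edge_key(v[2], v[3]), edge_key(v[3], v[1]))
    st <- c(s[1] != s[2], s[2] != s[3], s[3] != s[1])
    k[st]
  })))
  length(tab) == 0L || all(tab == 2L)
}

#' Jaccard overlap between two binary parcellations
#'
#' @param a,b `binary_parcellation` objects (or logical vectors) on the
#'   same vertex set.
#' @return Overlap coefficient |A intersect B| / |A union B| in [0, 1];
#'   defined as 1 when both masks are empty (documented convention).
#' @export
jaccard <- function(a, b) {
  ma <- if (inherits(a, "binary_parcellation")) a$mask else as.logical(a)
  mb <- if (inherits(b, "binary_parcellation")) b$mask else as.logical(b)
  if (length(ma) != length(mb)) {
    stop("masks must share the vertex set", call. = FALSE)
  }
  uni <- sum(ma | mb)
  if (uni == 0L) return(1)
  sum(ma & mb) / uni
}

#' Tangent-plane surface gradient magnitude
#'
#' At each vertex, the vertex and its one-ring neighbors are projected
#' onto the tangent plane (normal estimated from area-weighted incident
#' triangle normals, or angle-weighted via `normal_weighting`), and a
#' least-squares plane value ~ a + g . (u, v) is fitted; the gradient
#' magnitude is |g| in value units per mm. Exact for linear fields on
#' planar meshes. Vertices with fewer than 3 neighbors, missing values or
#' a rank-deficient (collinear) projected neighborhood are marked
#' undefined (`NA`).
#'
#' @param mesh A `surface_mesh`.
#' @param map Per-vertex numeric vector.
#' @param normal_weighting `"area"` (default) or `"angle"`.
#' @return A `gradient_map`: list with per-vertex `magnitude`.
#' @export
surface_gradient <- function(mesh, map, normal_weighting = c("area",
                                                             "angle")) {
  normal_weighting <- match.arg(normal_weighting)
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (length(map) != n) stop("map length mismatch", call. = FALSE)
  normals <- vertex_normals(mesh, normal_weighting)
  mag <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- mesh$neighbors[[i]]
    if (length(nb) < 3L) next
    vals <- map[c(i, nb)]
    if (any(!is.finite(vals))) next
    nrm <- normals[i, ]
    basis <- tangent_basis(nrm)
    off <- sweep(mesh$vertices[nb, , drop = FALSE], 2, mesh$vertices[i, ])
    uv <- off %*% basis
    X <- cbind(1, rbind(c(0, 0), uv))
    qr_x <- qr(X)
    if (qr_x$rank < 3L) next
    beta <- qr.coef(qr_x, vals)
    mag[i] <- sqrt(beta[2]^2 + beta[3]^2)
  }
  structure(list(magnitude = mag), class = "gradient_map")
}

vertex_normals <- function(mesh, weighting = "area") {
  tri <- mesh$triangles
  v <- mesh$vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c3 <- v[tri[, 3], , drop = FALSE]
  u <- b - a
  w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  # |cr| = 2 * area: area weighting keeps the raw cross products
  tri_n <- cr
  if (weighting == "angle") {
    tri_n <- cr / sqrt(rowSums(cr^2))
  }
  n <- nrow(v)
  out <- matrix(0, n, 3)
  for (j in 1:3) {
    idx <- tri[, j]
    wgt <- if (weighting == "angle") corner_angles(v, tri, j) else 1
    for (k in 1:3) {
      out[, k] <- out[, k] + tapply_add(tri_n[, k] * wgt, idx, n)
    }
  }
  out / pmax(sqrt(rowSums(out^2)), .Machine$double.eps)
}

corner_angles <- function(v, tri, j) {
  i0 <- tri[, j]
  i1 <- tri[, (j %% 3) + 1]
  i2 <- tri[, ((j + 1) %% 3) + 1]
  u <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
  w <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
  cosang <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
  acos(pmin(1, pmax(-1, cosang)))
}

tangent_basis <- function(nrm) {
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  cbind(e1, e2)
}

#' Threshold a gradient map into border candidates
#'
#' Marks vertices whose gradient magnitude meets the threshold. No
#' gap-filling or ridge-linking is attempted: gradient borders are
#' discontinuous by nature and completing them is an observer decision.
#'
#' @param gradient A `gradient_map` from [surface_gradient()].
#' @param threshold Non-negative gradient-magnitude threshold.
#' @return A `binary_parcellation` whose mask marks high-gradient
#'   vertices (undefined vertices are `FALSE`).
#' @export
gradient_borders <- function(gradient, threshold) {
  stopifnot(inherits(gradient, "gradient_map"))
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  }
  mag <- gradient$magnitude
  mask <- is.finite(mag) & mag >= threshold
  structure(list(mask = mask, source = list(kind = "gradient",
                                            threshold = threshold)),
            class = "binary_parcellation")
}
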