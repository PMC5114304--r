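#' Average a map over a cortical depth window
#'
#' Unweighted mean of the depth samples whose depth fraction lies inside
#' the inclusive window `[lo, hi]`; the default 20--80% window (7 of the 11
#' samples) avoids partial-volume contamination from white matter and CSF
#' at the extremes of the cortical ribbon.
#'
#' @param map Numeric matrix, vertices x 11 depths (fractions 0, 0.1, ...,
#'   1).
#' @param lo,hi Depth-fraction window bounds, both endpoints included.
#' @return Per-vertex numeric vector.
#' @export
depth_average <- function(map, lo = 0.2, hi = 0.8) {
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  fr <- depth_fractions()
  map <- as.matrix(map)
  if (ncol(map) != length(fr)) {
    stop("map must have one column per depth fraction (11)", call. = FALSE)
  }
  sel <- which(fr >= lo - 1e-9 & fr <= hi + 1e-9)
  if (!length(sel)) stop("empty depth window", call. = FALSE)
  rowMeans(map[, sel, drop = FALSE])
}

#' Remove curvature-correlated signal from a map
#'
#' Ordinary least-squares regression of the map on mesh curvature (with
#' intercept) over the non-missing vertices; returns the residuals shifted
#' back to the original map mean, so the output is mean-preserving and has
#' zero sample correlation with curvature. Gyral crowns and sulcal
#' fundi systematically bias myelin-sensitive maps; this removes the linear
#' component of that bias. Constant curvature leaves the map unchanged
#' (regression undefined; documented no-op).
#'
#' @param map Per-vertex numeric vector (`NA` = excluded).
#' @param curvature Per-vertex curvature on the same vertex set.
#' @return Residualized per-vertex map (`NA`s preserved).
#' @export
curvature_residualize <- function(map, curvature) {
  if (length(map) != length(curvature)) {
    stop("map and curvature must share the vertex set", call. = FALSE)
  }
  incl <- is.finite(map) & is.finite(curvature)
  if (sum(incl) < 3L) stop("need >= 3 included vertices", call. = FALSE)
  cv <- curvature[incl]
  if (stats::sd(cv) == 0) return(map)
  y <- map[incl]
  b <- stats::cov(y, cv) / stats::var(cv)
  a <- mean(y) - b * mean(cv)
  out <- map
  out[incl] <- y - (a + b * cv) + mean(y)
  out
}

#' Geodesic Gaussian smoothing by iterated diffusion
#'
#' Approximates convolution with a geodesic Gaussian kernel of the given
#' full width at half maximum by repeated conservative area-weighted
#' neighbor diffusion. Each step moves value between edge-connected
#' vertices with symmetric edge weights, so the global area-weighted mean
#' is conserved exactly and output values never leave the input range (a
#' discrete maximum principle). The iteration count is derived from the
#' target kernel variance and the measured per-step variance of the
#' diffusion stencil. `fwhm_mm = 0` is the identity. Missing (`NA`)
#' vertices are left untouched and take no part in the diffusion.
#'
#' @param mesh A `surface_mesh`.
#' @param map Per-vertex numeric vector.
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @param lambda Diffusion step size in (0, 1]; smaller values trade more
#'   iterations for a better Gaussian approximation.
#' @return Smoothed per-vertex map.
#' @export
geodesic_smooth <- function(mesh, map, fwhm_mm = 1.0, lambda = 0.5) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (length(fwhm_mm) != 1L || is.na(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  }
  if (length(map) != nrow(mesh$vertices)) {
    stop("map length must equal the vertex count", call. = FALSE)
  }
  if (fwhm_mm == 0) return(map)

  ok <- is.finite(map)
  e <- mesh_edges(mesh)
  keep <- ok[e[, 1]] & ok[e[, 2]]
  v1 <- e[keep, 1]
  v2 <- e[keep, 2]
  if (!length(v1)) return(map)
  a <- mesh$vertex_area
  w <- (a[v1] + a[v2]) / 2
  d2 <- rowSums((mesh$vertices[v1, , drop = FALSE] -
                   mesh$vertices[v2, , drop = FALSE])^2)

  # normalizer keeping every update a convex combination
  wsum <- tapply_add(w, v1, length(a)) + tapply_add(w, v2, length(a))
  D <- max(wsum[ok] / a[ok])

  # mean per-step kernel variance along one tangent axis:
  # each vertex mixes neighbor j with coefficient c_ij = lambda*w_ij/(a_i*D)
  step_var_i <- (lambda / D) *
    (tapply_add(w * d2, v1, length(a)) + tapply_add(w * d2, v2, length(a))) /
    (2 * a)
  s_bar <- mean(step_var_i[ok])
  sigma2 <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  iters <- max(1L, as.integer(round(sigma2 / s_bar)))

  x <- map
  for (k in seq_len(iters)) {
    flux <- w * (x[v2] - x[v1])
    dx <- tapply_add(flux, v1, length(a)) - tapply_add(flux, v2, length(a))
    x[ok] <- x[ok] + (lambda / D) * dx[ok] / a[ok]
  }
  x
}

#' Region summary statistics
#'
#' Mean, inter-vertex standard error (sample sd / sqrt(n)) and vertex count
#' of a per-vertex map over one ROI; `NA` (excluded/unfittable) vertices do
#' not enter `n`.
#'
#' @param map Per-vertex numeric vector.
#' @param atlas An `roi_atlas`.
#' @param roi Region label or name.
#' @return List with `mean`, `se`, `n`.
#' @export
roi_stats <- function(map, atlas, roi) {
  idx <- roi_vertices(atlas, roi)
  vals <- map[idx]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop("region is empty after exclusion", call. = FALSE)
  }
  n <- length(vals)
  list(mean = mean(vals),
       se = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
       n = n)
}
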