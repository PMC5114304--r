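#' Rescale a value distribution to the unit interval
#'
#' Linear map sending the 3rd percentile to 0 and the 97th percentile to 1
#' (percentiles by linear interpolation). Values outside that range map
#' outside [0, 1] and are deliberately not clamped: only the
#' full-width-half-maximum computation consumes the rescaled distribution,
#' and clamping would distort its half-maximum crossings.
#'
#' @param values Per-vertex numeric vector (`NA` ignored for the
#'   percentiles, preserved in the output).
#' @return Dimensionless rescaled vector.
#' @export
rescale_unit <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) {
    stop("degenerate distribution: need >= 2 distinct values",
         call. = FALSE)
  }
  q <- stats::quantile(v, c(0.03, 0.97), names = FALSE, type = 7)
  if (q[1] == q[2]) {
    stop("degenerate distribution: 3rd and 97th percentiles coincide",
         call. = FALSE)
  }
  (values - q[1]) / (q[2] - q[1])
}

#' Full width at half maximum of a value distribution
#'
#' Width between the outermost crossings of half the modal density of the
#' value histogram. The density is estimated either from a
#' Freedman--Diaconis histogram or from a Gaussian kernel density with
#' Silverman's bandwidth; crossings are located by linear interpolation.
#'
#' @param values Numeric vector (>= 100 values recommended).
#' @param method `"kde"` (default) or `"histogram"`.
#' @return Width in the units of `values`.
#' @examples
#' x <- stats::rnorm(1e5)
#' estimate_fwhm(x) / 2.3548  # ~ 1 (Gaussian sd)
#' @export
estimate_fwhm <- function(values, method = c("kde", "histogram")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) {
    stop("degenerate distribution: FWHM undefined", call. = FALSE)
  }
  if (method == "kde") {
    d <- stats::density(v, bw = "nrd0", n = 2048)
    xs <- d$x
    ys <- d$y
  } else {
    h <- graphics::hist(v, breaks = "FD", plot = FALSE)
    xs <- h$mids
    ys <- h$density
  }
  peak <- which.max(ys)
  half <- ys[peak] / 2
  above <- ys >= half
  if (above[1] || above[length(above)]) {
    stop(paste0(
      "FWHM estimation failed: density does not fall below half maximum ",
      "on both sides of the mode (half = ", signif(half, 4), ")"
    ), call. = FALSE)
  }
  left <- min(which(above))
  right <- max(which(above))
  x_left <- interp_crossing(xs[left - 1], xs[left], ys[left - 1], ys[left],
                            half)
  x_right <- interp_crossing(xs[right], xs[right + 1], ys[right],
                             ys[right + 1], half)
  x_right - x_left
}

interp_crossing <- function(x0, x1, y0, y1, level) {
  if (y1 == y0) return((x0 + x1) / 2)
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}

#' Summary of a cortical value distribution
#'
#' Percentile anchors, FWHM before and after unit rescaling, and the
#' cumulative-AUC quantile function used for threshold parcellation.
#'
#' @param values Per-vertex numeric vector.
#' @param method FWHM estimator, see [estimate_fwhm()].
#' @return A `distribution_summary` with `p3`, `p97`, `fwhm_raw`,
#'   `fwhm_rescaled` and `auc_quantile` (a function of pct in [0, 100]).
#' @export
distribution_summary <- function(values, method = c("kde", "histogram")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  q <- stats::quantile(v, c(0.03, 0.97), names = FALSE, type = 7)
  structure(
    list(p3 = q[1], p97 = q[2],
         fwhm_raw = estimate_fwhm(values, method),
         fwhm_rescaled = estimate_fwhm(rescale_unit(values), method),
         auc_quantile = function(pct) auc_threshold(values, pct)),
    class = "distribution_summary"
  )
}

#' FWHM-normalized coefficient of variation per vertex
#'
#' Per-vertex sample standard deviation over mean across units (subjects
#' for `kind = "inter"`, sessions for `kind = "intra"`), divided by the
#' full-width-half-maximum of the rescaled across-unit average cortical
#' distribution. For the intra kind the per-subject scan-rescan COV is
#' computed first and then averaged across the rescanned subjects.
#'
#' @param stack For `kind = "inter"`: a vertices x subjects matrix. For
#'   `kind = "intra"`: a list of vertices x sessions matrices, one per
#'   rescanned subject.
#' @param fwhm_rescaled Dimensionless FWHM of the rescaled average-map
#'   distribution (see [distribution_summary()]).
#' @param kind `"inter"` or `"intra"`.
#' @return A `reliability_maps` object: per-vertex `cov` (NA where the
#'   mean is non-positive or a unit is missing) and `kind`.
#' @export
cov_vertexwise <- function(stack, fwhm_rescaled, kind = c("inter", "intra")) {
  kind <- match.arg(kind)
  check_scalar_positive(fwhm_rescaled, "fwhm_rescaled")
  if (kind == "inter") {
    stack <- as.matrix(stack)
    if (ncol(stack) < 2L) stop("need >= 2 subjects", call. = FALSE)
    cov <- raw_cov(stack) / fwhm_rescaled
  } else {
    if (!is.list(stack) || !length(stack)) {
      stop("intra kind expects a list of per-subject session matrices",
           call. = FALSE)
    }
    per_subject <- lapply(stack, function(m) {
      m <- as.matrix(m)
      if (ncol(m) < 2L) stop("need >= 2 sessions per subject",
                             call. = FALSE)
      raw_cov(m)
    })
    cov <- Reduce(`+`, per_subject) / length(per_subject) / fwhm_rescaled
  }
  structure(list(cov = as.numeric(cov), kind = kind),
            class = "reliability_maps")
}

raw_cov <- function(m) {
  mu <- rowMeans(m)
  out <- row_sds(m) / mu
  bad <- !is.finite(out) | !is.finite(mu) | mu <= 0
  bad[is.na(bad)] <- TRUE
  out[bad] <- NA_real_
  out
}

#' Parcellability variation per vertex
#'
#' The average scan-rescan standard deviation divided by the FWHM of the
#' average cortical distribution before rescaling. Lower values mean a
#' vertex can be located more reliably within the cortical histogram,
#' i.e., higher parcellability.
#'
#' @param scanrescan_sd Per-vertex scan-rescan sd averaged across the
#'   rescanned subjects (see [scan_rescan_sd()]).
#' @param fwhm_raw FWHM of the average distribution in the parameter's own
#'   units.
#' @return Per-vertex PV (dimensionless).
#' @export
pv_vertexwise <- function(scanrescan_sd, fwhm_raw) {
  check_scalar_positive(fwhm_raw, "fwhm_raw")
  scanrescan_sd / fwhm_raw
}

#' Average scan-rescan standard deviation
#'
#' @param stack List of vertices x sessions matrices, one per rescanned
#'   subject.
#' @return Per-vertex sd averaged across subjects.
#' @export
scan_rescan_sd <- function(stack) {
  per_subject <- lapply(stack, function(m) row_sds(as.matrix(m)))
  Reduce(`+`, per_subject) / length(per_subject)
}

#' Contrast-to-noise ratio per unit scan time
#'
#' For each vertex of an ROI, the absolute difference between its value and
#' a reference value from the designated lightly myelinated neighbor
#' region, divided by the pooled inter-vertex sd of both regions (the noise
#' estimate) and by the square root of the scan duration in minutes. The
#' reference is a seeded per-vertex random draw from the neighbor region
#' (faithful to a randomly selected reference vertex) or, for fully
#' deterministic pipelines, the neighbor region's median.
#'
#' @param map Per-vertex numeric vector.
#' @param atlas An `roi_atlas`.
#' @param roi Region label or name.
#' @param minutes Scan duration attributed to the parameter (minutes > 0).
#' @param ref_mode `"random_vertex"` or `"region_median"`.
#' @param seed Seed for the random reference draws.
#' @return List with per-vertex `cnr` (NA off the ROI), and the ROI `mean`,
#'   inter-vertex `se` and `n`.
#' @export
cnr_per_time <- function(map, atlas, roi, minutes,
                         ref_mode = c("random_vertex", "region_median"),
                         seed = 1L) {
  ref_mode <- match.arg(ref_mode)
  check_scalar_positive(minutes, "minutes")
  lab <- resolve_label(atlas, roi)
  nb_lab <- atlas$table$neighbor_label[match(lab, atlas$table$label)]
  if (is.na(nb_lab)) {
    stop("region has no designated neighbor region", call. = FALSE)
  }
  roi_idx <- roi_vertices(atlas, lab)
  nb_idx <- roi_vertices(atlas, nb_lab)
  roi_idx <- roi_idx[is.finite(map[roi_idx])]
  nb_idx <- nb_idx[is.finite(map[nb_idx])]
  if (!length(roi_idx) || !length(nb_idx)) {
    stop("region or neighbor empty after exclusion", call. = FALSE)
  }
  pooled <- map[c(roi_idx, nb_idx)]
  sigma <- stats::sd(pooled)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate contrast: pooled sd is zero", call. = FALSE)
  }
  ref <- if (ref_mode == "region_median") {
    rep(stats::median(map[nb_idx]), length(roi_idx))
  } else {
    with_seed(seed,
              map[nb_idx[sample.int(length(nb_idx), length(roi_idx),
                                    replace = TRUE)]])
  }
  cnr_roi <- abs(map[roi_idx] - ref) / sigma / sqrt(minutes)
  cnr <- rep(NA_real_, length(map))
  cnr[roi_idx] <- cnr_roi
  n <- length(cnr_roi)
  list(cnr = cnr, mean = mean(cnr_roi),
       se = if (n > 1) stats::sd(cnr_roi) / sqrt(n) else 0, n = n)
}

#' Depth-resolved vertex-wise Pearson correlation
#'
#' Pearson correlation between two parameter maps over the included
#' vertices, at each of the 11 cortical depths and for the depth-averaged
#' maps.
#'
#' @param map_a,map_b Vertices x 11 depth matrices.
#' @param mask Logical exclusion mask (`TRUE` = excluded), e.g. from
#'   [exclusion_mask()].
#' @param lo,hi Depth window for the depth-averaged correlation.
#' @return List with `by_depth` (length 11, NA where undefined), `overall`
#'   and the included vertex count `n`.
#' @export
depthwise_correlation <- function(map_a, map_b,
                                  mask = rep(FALSE, nrow(map_a)),
                                  lo = 0.2, hi = 0.8) {
  map_a <- as.matrix(map_a)
  map_b <- as.matrix(map_b)
  stopifnot(nrow(map_a) == nrow(map_b), ncol(map_a) == ncol(map_b))
  incl <- !mask & apply(is.finite(map_a), 1, all) &
    apply(is.finite(map_b), 1, all)
  if (sum(incl) < 3L) stop("need >= 3 included vertices", call. = FALSE)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  by_depth <- vapply(seq_len(ncol(map_a)), function(d) {
    safe_cor(map_a[incl, d], map_b[incl, d])
  }, numeric(1))
  overall <- safe_cor(depth_average(map_a, lo, hi)[incl],
                      depth_average(map_b, lo, hi)[incl])
  list(by_depth = by_depth, overall = overall, n = sum(incl))
}
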