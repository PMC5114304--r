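#' Default ROI layout
#'
#' Region set emulating a myeloarchitectonic atlas: heavily myelinated
#' primary areas (somatosensory/motor strip BA1-BA4, visual V1/V2, MT, and
#' the transverse temporal gyrus and sulcus of the auditory core), three
#' moderately myelinated premotor/frontal areas (BA6, BA44, BA45) and one
#' lightly myelinated region (retrosplenial cortex analog). A lightly
#' myelinated background region surrounding the ROIs is always added by
#' [build_atlas()] and serves as the contrast reference neighbor.
#'
#' @return A data.frame with columns `name` and `class`
#'   (`heavy`/`moderate`/`light`), one row per region.
#' @export
default_roi_layout <- function() {
  data.frame(
    name = c("BA1", "BA2", "BA3", "BA4", "V1", "V2", "MT", "gTT", "sTT",
             "BA6", "BA44", "BA45", "RSC"),
    class = c(rep("heavy", 9), rep("moderate", 3), "light"),
    stringsAsFactors = FALSE
  )
}

#' Build an ROI atlas on a surface mesh
#'
#' Places the requested regions as disjoint geodesic (graph-distance) caps
#' with well-separated seed vertices chosen by farthest-point sampling, and
#' labels all remaining vertices as lightly myelinated background
#' (label 0). Every region therefore shares mesh edges with the background,
#' which is set as its `neighbor_label` reference for contrast-to-noise
#' computations.
#'
#' @param mesh A `surface_mesh`.
#' @param layout A data.frame with columns `name` and `class`
#'   (`heavy`/`moderate`/`light`); defaults to [default_roi_layout()].
#' @param radius_frac Cap radius as a fraction of the minimum seed
#'   separation (graph distance). The default keeps the labeled regions a
#'   minority of the surface, as distinctly myelinated areas are of the
#'   cortex, with disjoint caps surrounded by background.
#' @return An object of class `roi_atlas`: `labels` (per-vertex integer,
#'   0 = background) and `table` (label, name, class, neighbor_label,
#'   background flag).
#' @examples
#' atlas <- build_atlas(build_mesh("icosphere", 3))
#' table(atlas$labels)[1:3]
#' @export
build_atlas <- function(mesh, layout = default_roi_layout(),
                        radius_frac = 0.32) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.data.frame(layout) || !all(c("name", "class") %in% names(layout))) {
    stop("`layout` must be a data.frame with columns name, class",
         call. = FALSE)
  }
  if (!all(layout$class %in% c("heavy", "moderate", "light"))) {
    stop("region class must be heavy, moderate or light", call. = FALSE)
  }
  n_regions <- nrow(layout)
  if (n_regions < 2L || !any(layout$class == "heavy") ||
      !any(layout$class == "light")) {
    stop("layout must name at least 2 regions incl. >= 1 heavy and 1 light",
         call. = FALSE)
  }
  n <- nrow(mesh$vertices)
  if (n_regions + 1L > n %/% 4L) {
    stop("layout error: mesh too small to host the requested regions",
         call. = FALSE)
  }

  seeds <- farthest_point_seeds(mesh, n_regions)
  dists <- vapply(seeds, function(s) graph_distances(mesh, s), numeric(n))
  min_sep <- min(apply(utils::combn(n_regions, 2), 2,
                       function(p) dists[seeds[p[2]], p[1]]))
  if (radius_frac <= 0 || radius_frac >= 0.5) {
    stop("`radius_frac` must lie in (0, 0.5) to keep caps disjoint",
         call. = FALSE)
  }
  radius <- floor(radius_frac * min_sep)
  if (radius < 1) {
    stop("layout error: regions cannot be hosted contiguously on this mesh",
         call. = FALSE)
  }
  nearest <- apply(dists, 1, which.min)
  nearest_d <- dists[cbind(seq_len(n), nearest)]
  labels <- ifelse(nearest_d <= radius, nearest, 0L)

  tab <- data.frame(
    label = c(0L, seq_len(n_regions)),
    name = c("BG", layout$name),
    class = c("light", layout$class),
    neighbor_label = c(NA_integer_, rep(0L, n_regions)),
    background = c(TRUE, rep(FALSE, n_regions)),
    stringsAsFactors = FALSE
  )
  atlas <- structure(list(labels = as.integer(labels), table = tab),
                     class = "roi_atlas")
  validate_atlas(mesh, atlas)
  atlas
}

# deterministic farthest-point sampling over graph distance
farthest_point_seeds <- function(mesh, k) {
  n <- nrow(mesh$vertices)
  seeds <- 1L
  mind <- graph_distances(mesh, 1L)
  while (length(seeds) < k) {
    nxt <- which.max(mind)
    seeds <- c(seeds, nxt)
    mind <- pmin(mind, graph_distances(mesh, nxt))
  }
  seeds
}

# breadth-first hop distances from one vertex
graph_distances <- function(mesh, from) {
  n <- nrow(mesh$vertices)
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- unique(unlist(mesh$neighbors[frontier]))
    nxt <- nxt[!is.finite(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

#' Validate ROI-atlas invariants
#'
#' Every vertex labeled, every table label non-empty on the mesh, and every
#' region's neighbor reference an existing lightly myelinated region sharing
#' at least one mesh edge with it.
#'
#' @param mesh A `surface_mesh`.
#' @param atlas An `roi_atlas`.
#' @return The atlas, invisibly; stops on violation.
#' @export
validate_atlas <- function(mesh, atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  labels <- atlas$labels
  if (length(labels) != nrow(mesh$vertices) || anyNA(labels)) {
    stop("every vertex must carry a label", call. = FALSE)
  }
  tab <- atlas$table
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]
    if (!any(labels == lab)) {
      stop(sprintf("region '%s' is empty on the mesh", tab$name[i]),
           call. = FALSE)
    }
    nb_lab <- tab$neighbor_label[i]
    if (!is.na(nb_lab)) {
      j <- match(nb_lab, tab$label)
      if (is.na(j) || tab$class[j] != "light") {
        stop(sprintf("neighbor of '%s' must be an existing light region",
                     tab$name[i]), call. = FALSE)
      }
      if (!regions_share_edge(mesh, labels, lab, nb_lab)) {
        stop(sprintf("region '%s' shares no edge with its neighbor region",
                     tab$name[i]), call. = FALSE)
      }
    }
  }
  invisible(atlas)
}

regions_share_edge <- function(mesh, labels, a, b) {
  e <- mesh_edges(mesh)
  la <- labels[e[, 1]]
  lb <- labels[e[, 2]]
  any((la == a & lb == b) | (la == b & lb == a))
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("roi_atlas: %d regions + background over %d vertices\n",
              sum(!x$table$background), length(x$labels)))
  invisible(x)
}

#' Vertices belonging to an ROI
#'
#' @param atlas An `roi_atlas`.
#' @param roi Region label (integer) or region name.
#' @return Integer vector of vertex indices.
#' @export
roi_vertices <- function(atlas, roi) {
  which(atlas$labels == resolve_label(atlas, roi))
}

resolve_label <- function(atlas, roi) {
  if (is.character(roi)) {
    lab <- atlas$table$label[match(roi, atlas$table$name)]
    if (is.na(lab)) stop(sprintf("unknown region '%s'", roi), call. = FALSE)
    return(lab)
  }
  if (!roi %in% atlas$table$label) {
    stop(sprintf("unknown region label %s", roi), call. = FALSE)
  }
  as.integer(roi)
}
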