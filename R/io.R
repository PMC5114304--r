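# Minimal GIFTI 1.0 reader/writer (ASCII encoding) plus CSV/YAML helpers.
# GIFTI is the XML-based geometry format of the neuroimaging surface world;
# only the subset needed here is supported: POINTSET + TRIANGLE arrays for
# surfaces and one or more float32 arrays for per-vertex metrics.

gifti_header <- function() {
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         "<!DOCTYPE GIFTI SYSTEM \"http://www.nitrc.org/frs/download.php/",
         "115/gifti.dtd\">\n")
}

gifti_data_array <- function(values, intent, datatype) {
  dims <- dim(values)
  if (is.null(dims)) dims <- c(length(values), 1L)
  fmt <- if (datatype == "NIFTI_TYPE_INT32") {
    function(x) sprintf("%d", x)
  } else {
    function(x) sprintf("%.9g", x)
  }
  # row-major text payload
  payload <- paste(apply(values, 1, function(r) paste(fmt(r), collapse = " ")),
                   collapse = "\n")
  sprintf(paste0(
    "<DataArray Intent=\"%s\" DataType=\"%s\" ",
    "ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\" ",
    "Dim0=\"%d\" Dim1=\"%d\" Encoding=\"ASCII\" Endian=\"LittleEndian\" ",
    "ExternalFileName=\"\" ExternalFileOffset=\"\">\n",
    "<Data>%s</Data>\n</DataArray>"
  ), intent, datatype, dims[1], dims[2], payload)
}

#' Write a surface mesh as a GIFTI surface file
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path (conventionally `.surf.gii`).
#' @return The path, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  doc <- paste0(
    gifti_header(),
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"2\">\n",
    gifti_data_array(mesh$vertices, "NIFTI_INTENT_POINTSET",
                     "NIFTI_TYPE_FLOAT32"), "\n",
    gifti_data_array(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                     "NIFTI_TYPE_INT32"), "\n",
    "</GIFTI>\n"
  )
  writeLines(doc, path)
  invisible(path)
}

#' Read a GIFTI surface file
#'
#' @param path Path to a `.surf.gii` file with ASCII-encoded POINTSET and
#'   TRIANGLE arrays.
#' @return A `surface_mesh` (adjacency, areas and curvature recomputed).
#' @export
read_gifti_surface <- function(path) {
  arrays <- read_gifti_arrays(path)
  pts <- arrays[["NIFTI_INTENT_POINTSET"]]
  tri <- arrays[["NIFTI_INTENT_TRIANGLE"]]
  if (is.null(pts) || is.null(tri)) {
    stop("GIFTI parse error: missing POINTSET or TRIANGLE DataArray",
         call. = FALSE)
  }
  finish_mesh(pts, matrix(as.integer(tri), nrow(tri)) + 1L)
}

#' Write per-vertex metric values as a GIFTI metric file
#'
#' @param values Numeric vector or vertices x k matrix.
#' @param path Output path (conventionally `.func.gii`).
#' @return The path, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  values <- as.matrix(values)
  doc <- paste0(
    gifti_header(),
    sprintf("<GIFTI Version=\"1.0\" NumberOfDataArrays=\"%d\">\n",
            ncol(values)),
    paste(vapply(seq_len(ncol(values)), function(j) {
      gifti_data_array(values[, j, drop = FALSE], "NIFTI_INTENT_NONE",
                       "NIFTI_TYPE_FLOAT32")
    }, character(1)), collapse = "\n"), "\n",
    "</GIFTI>\n"
  )
  writeLines(doc, path)
  invisible(path)
}

#' Read a GIFTI metric file
#'
#' @param path Path to a `.func.gii` file.
#' @return Numeric matrix, vertices x arrays.
#' @export
read_gifti_metric <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) {
    stop("GIFTI parse error: no DataArray elements", call. = FALSE)
  }
  cols <- lapply(arrays, parse_gifti_array)
  do.call(cbind, lapply(cols, as.numeric))
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  out <- list()
  for (a in arrays) {
    out[[xml2::xml_attr(a, "Intent")]] <- parse_gifti_array(a)
  }
  out
}

parse_gifti_array <- function(a) {
  enc <- xml2::xml_attr(a, "Encoding")
  if (!identical(enc, "ASCII")) {
    stop(sprintf("GIFTI parse error: unsupported Encoding '%s'", enc),
         call. = FALSE)
  }
  d0 <- as.integer(xml2::xml_attr(a, "Dim0"))
  d1 <- as.integer(xml2::xml_attr(a, "Dim1"))
  if (is.na(d1)) d1 <- 1L
  txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
  vals <- scan(text = txt, quiet = TRUE)
  if (length(vals) != d0 * d1) {
    stop("GIFTI parse error: Data length disagrees with Dim0 x Dim1",
         call. = FALSE)
  }
  matrix(vals, nrow = d0, ncol = d1, byrow = TRUE)
}

#' Write a flat vertex table as CSV
#'
#' Long-format export of per-vertex values: one row per (vertex, depth,
#' parameter).
#'
#' @param df data.frame with at least `vertex_id`, `label`, `depth`,
#'   `parameter`, `value`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_vertex_table <- function(df, path) {
  check_vertex_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat vertex table from CSV
#'
#' @param path CSV path.
#' @return data.frame; stops with the name of any missing required column.
#' @export
read_vertex_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_vertex_table(df)
  df
}

check_vertex_table <- function(df) {
  required <- c("vertex_id", "label", "depth", "parameter", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("vertex table schema error: missing column '%s'",
                 missing[1]), call. = FALSE)
  }
  invisible(df)
}

#' Flatten per-depth session maps into a vertex table
#'
#' @param session A `subject_session`.
#' @param atlas An `roi_atlas`.
#' @return Long data.frame (vertex_id, label, depth, parameter, value).
#' @export
session_vertex_table <- function(session, atlas) {
  stopifnot(inherits(session, "subject_session"))
  fr <- depth_fractions()
  out <- lapply(names(session$maps), function(p) {
    m <- session$maps[[p]]$depths
    data.frame(
      vertex_id = rep(seq_len(nrow(m)), times = ncol(m)),
      label = rep(atlas$labels, times = ncol(m)),
      depth = rep(fr, each = nrow(m)),
      parameter = p,
      value = as.vector(m)
    )
  })
  do.call(rbind, out)
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; fields override [experiment_config()] defaults.
#' @return An `experiment_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' Write an experiment configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
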