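#' Labelled triangle surfaces
#'
#' A labelled surface couples a triangle mesh (vertices in micrometres, faces
#' as vertex-index triples) with one marker-density value per face (e.g. an
#' apical-membrane indicator) and a projection center. It is the input of
#' [project_to_sphere()].
#'
#' @param vertices Numeric matrix or data frame with columns `x`, `y`, `z`.
#' @param faces Integer matrix or data frame with columns `v1`, `v2`, `v3`
#'   (1-based vertex indices).
#' @param face_values Numeric vector, one marker density per face.
#' @param center Optional projection center (length-3 numeric); when `NULL`
#'   the area-weighted centroid ([estimate_center()]) is used.
#' @return An object of class `labeled_surface`.
#' @export
labeled_surface <- function(vertices, faces, face_values, center = NULL) {
  vertices <- as.matrix(as.data.frame(vertices)[, 1:3])
  faces <- as.matrix(as.data.frame(faces)[, 1:3])
  storage.mode(faces) <- "integer"
  colnames(vertices) <- c("x", "y", "z")
  colnames(faces) <- c("v1", "v2", "v3")
  if (length(face_values) != nrow(faces)) {
    stop("face_values must have one entry per face", call. = FALSE)
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range", call. = FALSE)
  }
  obj <- structure(list(vertices = vertices, faces = faces,
                        face_values = as.numeric(face_values),
                        center = center),
                   class = "labeled_surface")
  if (is.null(center)) obj$center <- estimate_center(obj)
  obj
}

#' @export
print.labeled_surface <- function(x, ...) {
  cat("<labeled_surface>", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces, center =",
      paste(signif(x$center, 4), collapse = ", "), "\n")
  invisible(x)
}

face_geometry <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  centroid <- (p1 + p2 + p3) / 3
  list(p1 = p1, p2 = p2, p3 = p3, area = area, centroid = centroid)
}

#' Area-weighted centroid of a labelled surface
#'
#' Used as the default projection center when none is supplied.
#'
#' @param surface A [labeled_surface()].
#' @return A length-3 numeric vector (micrometres).
#' @export
estimate_center <- function(surface) {
  stopifnot(inherits(surface, "labeled_surface"))
  if (nrow(surface$faces) == 0L) stop("empty mesh", call. = FALSE)
  g <- face_geometry(surface)
  as.numeric(colSums(g$centroid * g$area) / sum(g$area))
}

#' Read a Wavefront OBJ mesh as a labelled surface
#'
#' Minimal ASCII reader for `v`/`f` records (triangular faces; `a/b/c` index
#' syntax accepted, only the vertex index is used). Face marker values come
#' from a sidecar CSV keyed by face index (columns `face`, `value`); when no
#' sidecar is given all faces get value 1.
#'
#' @param path OBJ file path.
#' @param values_path Optional sidecar CSV with columns `face`, `value`.
#' @param center Optional projection center.
#' @return A [labeled_surface()].
#' @export
read_surface_obj <- function(path, values_path = NULL, center = NULL) {
  lines <- readLines(path, warn = FALSE)
  vt <- grep("^v\\s", lines, value = TRUE)
  ft <- grep("^f\\s", lines, value = TRUE)
  if (length(vt) == 0L || length(ft) == 0L) stop("no mesh in ", path, call. = FALSE)
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vt)), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", ft)), "\\s+"),
                                 function(p) {
    if (length(p) != 3L) stop("only triangular faces supported", call. = FALSE)
    as.integer(vapply(strsplit(p, "/"), `[[`, "", 1L))
  }))
  labeled_surface(verts, faces, face_values_from_sidecar(values_path, nrow(faces)),
                  center = center)
}

#' Read an ASCII PLY mesh as a labelled surface
#'
#' Minimal reader for ASCII PLY with `vertex` (x, y, z leading properties) and
#' `face` (vertex_indices list, triangles, 0-based) elements.
#'
#' @inheritParams read_surface_obj
#' @return A [labeled_surface()].
#' @export
read_surface_ply <- function(path, values_path = NULL, center = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file", call. = FALSE)
  if (!any(grepl("format ascii", lines))) stop("only ASCII PLY supported", call. = FALSE)
  endh <- match("end_header", lines)
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines[1:endh], value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines[1:endh], value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  verts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                 function(p) {
    if (as.integer(p[1]) != 3L) stop("only triangular faces supported", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }))
  labeled_surface(verts, faces, face_values_from_sidecar(values_path, nf),
                  center = center)
}

face_values_from_sidecar <- function(values_path, n_faces) {
  if (is.null(values_path)) return(rep(1, n_faces))
  tab <- readr::read_csv(values_path, show_col_types = FALSE)
  if (!all(c("face", "value") %in% names(tab))) {
    stop("sidecar CSV needs columns face, value", call. = FALSE)
  }
  vals <- rep(NA_real_, n_faces)
  vals[tab$face] <- tab$value
  if (anyNA(vals)) stop("sidecar CSV misses values for some faces", call. = FALSE)
  vals
}
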