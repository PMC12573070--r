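#' Serialize a mesh to JSON and back
#'
#' Plain-text mesh container: vertices, triangle indices, and boundary flags.
#'
#' @param mesh An `endo_mesh`.
#' @param path JSON file path.
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns the
#'   mesh.
#' @export
write_mesh <- function(mesh, path) {
  jsonlite::write_json(
    list(vertices = mesh$vertices, triangles = mesh$triangles,
         boundary = mesh$boundary),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(vertices = matrix(as.numeric(d$vertices), ncol = 2),
         triangles = matrix(as.integer(d$triangles), ncol = 3),
         boundary = as.logical(d$boundary),
         n_vertices = nrow(d$vertices)),
    class = "endo_mesh"
  )
}

#' Export a precision matrix in Matrix Market format
#'
#' @param Q Sparse symmetric matrix (e.g. [matern_precision()] output).
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_precision_mtx <- function(Q, path) {
  Matrix::writeMM(as(Q, "generalMatrix"), path)
  invisible(path)
}
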