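#' Build a triangular mesh for SPDE fields
#'
#' Constructs a Delaunay-based triangulation of the (deduplicated) data
#' locations, extended by a rectangular buffer ring so that boundary effects of
#' the Markov approximation are pushed away from the data, and refined by
#' long-edge midpoint insertion until no triangle edge exceeds `max_edge`.
#'
#' @param points Data frame or matrix with `x`, `y` columns in km.
#' @param cutoff Minimum site separation (km): points closer than this to an
#'   already-kept site are merged into it.
#' @param max_edge Maximum allowed triangle edge length (km).
#' @param extension Width (km) of the rectangular buffer added around the
#'   bounding box of the points. `0` disables the buffer.
#' @return An object of class `endo_mesh`: list with `vertices` (n x 2 matrix,
#'   km), `triangles` (m x 3 integer matrix, counterclockwise), `boundary`
#'   (logical flag per vertex, convex-hull membership) and `n_vertices`.
#' @examples
#' sq <- data.frame(x = c(0, 100, 0, 100), y = c(0, 0, 100, 100))
#' m <- build_mesh(sq, cutoff = 1, max_edge = 200, extension = 0)
#' nrow(m$triangles) # 2
#' @export
build_mesh <- function(points, cutoff = 25, max_edge = 150, extension = 300) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) abort("non-finite coordinates in mesh points")
  if (cutoff < 0 || max_edge <= 0 || extension < 0)
    abort("cutoff/extension must be >= 0 and max_edge > 0")

  keep <- dedup_points(pts, cutoff)
  if (nrow(keep) < 3 || collinear(keep))
    abort("need at least 3 non-collinear points after cutoff deduplication")

  verts <- keep
  if (extension > 0) {
    bb <- rbind(range(pts[, 1]), range(pts[, 2]))
    ring <- rect_ring(bb[1, ] + c(-extension, extension),
                      bb[2, ] + c(-extension, extension),
                      spacing = max_edge)
    verts <- rbind(verts, ring)
    verts <- dedup_points(verts, min(cutoff, max_edge / 4))
  }

  for (iter in seq_len(40)) {
    tri <- delaunay(verts)
    ed <- mesh_edges(verts, tri)
    long <- ed$len > max_edge * (1 + 1e-9)
    if (!any(long)) break
    mids <- (verts[ed$i[long], , drop = FALSE] +
               verts[ed$j[long], , drop = FALSE]) / 2
    mids <- dedup_points(mids, max_edge / 8)
    verts <- rbind(verts, mids)
  }

  hull <- grDevices::chull(verts)
  boundary <- seq_len(nrow(verts)) %in% hull
  structure(
    list(vertices = unname(verts), triangles = tri, boundary = boundary,
         n_vertices = nrow(verts)),
    class = "endo_mesh"
  )
}

# greedy sequential dedup: keep a point iff >= cutoff from every kept point
dedup_points <- function(pts, cutoff) {
  if (cutoff <= 0 || nrow(pts) < 2) return(pts)
  kept <- matrix(NA_real_, nrow(pts), 2)
  kept[1, ] <- pts[1, ]
  nk <- 1L
  for (i in 2:nrow(pts)) {
    d2 <- (kept[1:nk, 1] - pts[i, 1])^2 + (kept[1:nk, 2] - pts[i, 2])^2
    if (min(d2) >= cutoff^2) {
      nk <- nk + 1L
      kept[nk, ] <- pts[i, ]
    }
  }
  kept[1:nk, , drop = FALSE]
}

collinear <- function(pts) {
  if (nrow(pts) < 3) return(TRUE)
  a <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cr <- a[1, 1] * a[, 2] - a[1, 2] * a[, 1]
  # all cross products ~0 relative to scale -> collinear
  all(abs(cr) < 1e-9 * max(1, max(abs(a)))^2)
}

rect_ring <- function(xr, yr, spacing) {
  nx <- max(2, ceiling(diff(xr) / spacing) + 1)
  ny <- max(2, ceiling(diff(yr) / spacing) + 1)
  xs <- seq(xr[1], xr[2], length.out = nx)
  ys <- seq(yr[1], yr[2], length.out = ny)
  unique(rbind(
    cbind(xs, yr[1]), cbind(xs, yr[2]),
    cbind(xr[1], ys), cbind(xr[2], ys)
  ))
}

delaunay <- function(verts) {
  junk <- utils::capture.output(utils::capture.output(
    d <- suppressWarnings(
      deldir::deldir(verts[, 1], verts[, 2], suppressMsge = TRUE)
    ), type = "message"))
  tri <- deldir::triMat(d)
  if (is.null(dim(tri))) tri <- matrix(tri, nrow = 1)
  # enforce counterclockwise orientation (positive signed area)
  a <- verts[tri[, 1], , drop = FALSE]
  b <- verts[tri[, 2], , drop = FALSE]
  cc <- verts[tri[, 3], , drop = FALSE]
  s <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  flip <- s < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  if (any(abs(s) < 1e-12)) abort("degenerate (zero-area) triangle in mesh")
  unname(tri)
}

mesh_edges <- function(verts, tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt((verts[e[, 1], 1] - verts[e[, 2], 1])^2 +
                (verts[e[, 1], 2] - verts[e[, 2], 2])^2)
  list(i = e[, 1], j = e[, 2], len = len)
}

#' @method print endo_mesh
#' @export
print.endo_mesh <- function(x, ...) {
  cat("<endo_mesh> ", x$n_vertices, " vertices, ", nrow(x$triangles),
      " triangles\n", sep = "")
  invisible(x)
}

#' Projector matrix from mesh nodes to point locations
#'
#' Builds the sparse barycentric-interpolation matrix `A` such that `A %*% w`
#' evaluates the piecewise-linear field with node values `w` at each location.
#' Each row has at most 3 non-zeros summing to 1.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param locations Data frame/matrix with `x`, `y` columns (km).
#' @return Sparse `dgCMatrix`, `nrow(locations)` x `mesh$n_vertices`.
#' @export
mesh_projector <- function(mesh, locations) {
  loc <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  n <- nrow(loc)
  V <- mesh$vertices
  tri <- mesh$triangles
  rowi <- integer(0); colj <- integer(0); val <- numeric(0)
  unassigned <- seq_len(n)
  for (t in seq_len(nrow(tri))) {
    if (!length(unassigned)) break
    idx <- tri[t, ]
    b <- barycentric(V[idx, ], loc[unassigned, , drop = FALSE])
    inside <- rowSums(b >= -1e-9) == 3
    if (any(inside)) {
      pts <- unassigned[inside]
      bw <- pmax(b[inside, , drop = FALSE], 0)
      bw <- bw / rowSums(bw)
      rowi <- c(rowi, rep(pts, 3))
      colj <- c(colj, rep(idx, each = length(pts)))
      val <- c(val, as.vector(bw))
      unassigned <- unassigned[!inside]
    }
  }
  if (length(unassigned))
    abort(paste0("locations outside mesh hull: rows ",
                 paste(head(unassigned, 5), collapse = ", "),
                 if (length(unassigned) > 5) " ..."))
  Matrix::sparseMatrix(i = rowi, j = colj, x = val,
                       dims = c(n, mesh$n_vertices))
}

# barycentric coordinates of points p (k x 2) wrt triangle tv (3 x 2)
barycentric <- function(tv, p) {
  d <- (tv[2, 2] - tv[3, 2]) * (tv[1, 1] - tv[3, 1]) +
    (tv[3, 1] - tv[2, 1]) * (tv[1, 2] - tv[3, 2])
  l1 <- ((tv[2, 2] - tv[3, 2]) * (p[, 1] - tv[3, 1]) +
           (tv[3, 1] - tv[2, 1]) * (p[, 2] - tv[3, 2])) / d
  l2 <- ((tv[3, 2] - tv[1, 2]) * (p[, 1] - tv[3, 1]) +
           (tv[1, 1] - tv[3, 1]) * (p[, 2] - tv[3, 2])) / d
  cbind(l1, l2, 1 - l1 - l2)
}

#' Test whether locations fall inside the mesh hull
#'
#' @inheritParams mesh_projector
#' @return Logical vector, one entry per location.
#' @export
in_mesh_hull <- function(mesh, locations) {
  loc <- as.matrix(as.data.frame(locations)[, c("x", "y")])
  ok <- rep(FALSE, nrow(loc))
  for (t in seq_len(nrow(mesh$triangles))) {
    idx <- mesh$triangles[t, ]
    left <- which(!ok)
    if (!length(left)) break
    b <- barycentric(mesh$vertices[idx, ], loc[left, , drop = FALSE])
    ok[left[rowSums(b >= -1e-9) == 3]] <- TRUE
  }
  ok
}
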