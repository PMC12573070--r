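#' Finite-element matrices of a mesh
#'
#' Assembles the piecewise-linear (P1) mass and stiffness matrices used in the
#' SPDE representation of Matern fields. The consistent mass matrix `C_full`
#' and its mass-lumped diagonal variant `C` (row sums, stored as a vector) are
#' both returned; the precision assembly uses the lumped form, the standard
#' sparsity-preserving approximation.
#'
#' @param mesh An [build_mesh()] mesh.
#' @return Object of class `endo_fem`: list with `C` (numeric vector, lumped
#'   mass diagonal), `C_full` (sparse symmetric mass matrix), `G` (sparse
#'   symmetric stiffness matrix), `area` (total mesh area, km^2).
#' @export
fem_matrices <- function(mesh) {
  V <- mesh$vertices
  tri <- mesh$triangles
  m <- nrow(V)
  ii <- integer(0); jj <- integer(0); gg <- numeric(0); mm <- numeric(0)
  clump <- numeric(m)
  for (t in seq_len(nrow(tri))) {
    id <- tri[t, ]
    p <- V[id, ]
    # edge vectors opposite each vertex
    e <- p[c(3, 1, 2), ] - p[c(2, 3, 1), ]
    area2 <- p[1, 1] * e[1, 1] + p[2, 1] * e[2, 1] + p[3, 1] * e[3, 1]
    # area2 = 2*signed area via cross terms; recompute robustly:
    area <- 0.5 * abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2]))
    if (area <= 0) abort("degenerate triangle in FEM assembly")
    Ke <- (e %*% t(e)) / (4 * area)
    Me <- area / 12 * (matrix(1, 3, 3) + diag(3))
    ii <- c(ii, rep(id, 3))
    jj <- c(jj, rep(id, each = 3))
    gg <- c(gg, as.vector(Ke))
    mm <- c(mm, as.vector(Me))
    clump[id] <- clump[id] + area / 3
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = gg, dims = c(m, m))
  C_full <- Matrix::sparseMatrix(i = ii, j = jj, x = mm, dims = c(m, m))
  structure(
    list(C = clump, C_full = Matrix::forceSymmetric(C_full),
         G = Matrix::forceSymmetric(G), area = sum(clump)),
    class = "endo_fem"
  )
}

#' Matern hyperparameter container
#'
#' The range convention follows the GMRF literature for smoothness nu = 1 in
#' two dimensions: `rho` is the distance at which correlation has fallen to
#' about 0.14, `kappa = sqrt(8) / rho`, and the precision is scaled so the
#' stationary marginal variance equals `sigma^2` (`tau^2 = 1 / (4 pi kappa^2
#' sigma^2)`).
#'
#' @param range Correlation range rho in km (> 0).
#' @param sigma Marginal standard deviation (>= 0).
#' @return Object of class `endo_matern` with fields `range`, `sigma`,
#'   `kappa`.
#' @export
matern_hyper <- function(range, sigma) {
  if (!is.finite(range) || range <= 0) abort("Matern range must be > 0")
  if (!is.finite(sigma) || sigma < 0) abort("Matern sd must be >= 0")
  structure(list(range = range, sigma = sigma, kappa = sqrt(8) / range),
            class = "endo_matern")
}

#' Sparse Matern (nu = 1) precision matrix via the SPDE construction
#'
#' `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^{-1} G)` with the lumped mass
#' matrix `C`, i.e. the alpha = 2 finite-element GMRF approximation of a
#' Matern field, scaled so interior nodes have marginal variance `sigma^2`.
#'
#' @param fem [fem_matrices()] output.
#' @param hyper [matern_hyper()] hyperparameters; `sigma` must be > 0 (a
#'   zero-variance field should be excluded from the model, not given a
#'   degenerate precision).
#' @return Sparse symmetric positive-definite `dsCMatrix`.
#' @export
matern_precision <- function(fem, hyper) {
  if (hyper$sigma <= 0) abort("sigma must be > 0 for a proper precision")
  kappa <- hyper$kappa
  tau2 <- 1 / (4 * pi * kappa^2 * hyper$sigma^2)
  Ci <- Matrix::Diagonal(x = 1 / fem$C)
  Cd <- Matrix::Diagonal(x = fem$C)
  Q <- tau2 * (kappa^4 * Cd + 2 * kappa^2 * fem$G + fem$G %*% Ci %*% fem$G)
  Matrix::forceSymmetric(Q)
}

#' Draw a zero-mean Matern field at the mesh nodes
#'
#' One sample from the GMRF with precision [matern_precision()], via sparse
#' Cholesky back-substitution. `sigma = 0` returns the all-zero field.
#'
#' @param mesh Mesh (its FEM matrices are assembled internally, or pass a
#'   precomputed `fem`).
#' @param range,sigma Matern hyperparameters, km and sd.
#' @param seed Integer seed (optional; uses the current RNG state if `NULL`).
#' @param n Number of independent draws.
#' @param fem Optional precomputed [fem_matrices()].
#' @return Numeric vector of node values (or matrix `n_vertices x n`).
#' @export
sample_gp_field <- function(mesh, range, sigma, seed = NULL, n = 1,
                            fem = NULL) {
  if (!is.finite(range) || range <= 0) abort("range must be > 0")
  if (!is.finite(sigma) || sigma < 0) abort("sigma must be >= 0")
  m <- mesh$n_vertices
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) {
    out <- matrix(0, m, n)
    return(if (n == 1) out[, 1] else out)
  }
  if (is.null(fem)) fem <- fem_matrices(mesh)
  Q <- matern_precision(fem, matern_hyper(range, sigma))
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(m * n), m, n)
  x <- solve(ch, solve(ch, z, system = "Lt"), system = "Pt")
  x <- as.matrix(x)
  if (n == 1) x[, 1] else x
}
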