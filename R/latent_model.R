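#' Latent Gaussian model blocks
#'
#' A latent Gaussian model here is a Bernoulli (or Gaussian) observation model
#' whose logit-linked linear predictor is a sparse design matrix times a
#' latent vector with block-structured Gaussian prior: vague-Gaussian fixed
#' effects, Matern GMRF fields (one set of mesh-node weights each), and iid
#' random-effect blocks. Hyperparameters (field range/sd, iid sd) carry PC
#' priors and can be fixed or estimated.
#'
#' @param X Dense or sparse design matrix for fixed effects.
#' @param prec Prior precision for each fixed-effect column (vague default
#'   0.001, i.e. sd about 31.6 on the logit scale).
#' @param A Sparse projector (observations x mesh nodes), already multiplied
#'   by any covariate (e.g. scaled year for a spatially varying slope).
#' @param fem [fem_matrices()] for the mesh carrying the field.
#' @param range,sigma Initial (or fixed) Matern hyperparameters.
#' @param index Integer or factor giving the level of each observation for an
#'   iid block.
#' @param n_levels Number of levels (defaults to `max(index)` /
#'   `nlevels(index)`).
#' @param sd Initial (or fixed) iid standard deviation.
#' @param prior PC prior spec ([pc_prior_field()] / [pc_prior_iid()]).
#' @param estimate Should this block's hyperparameters enter the
#'   hyperparameter vector (`TRUE`) or stay fixed (`FALSE`)?
#' @name lgm_blocks
NULL

#' @rdname lgm_blocks
#' @export
block_fixed <- function(X, prec = 1e-3) {
  X <- as(as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  structure(list(type = "fixed", A = X, ncol = ncol(X), prec = prec),
            class = "endo_block")
}

#' @rdname lgm_blocks
#' @export
block_field <- function(A, fem, range = 342, sigma = 1,
                        prior = pc_prior_field(), estimate = TRUE) {
  structure(list(type = "field", A = A, ncol = ncol(A), fem = fem,
                 range = range, sigma = sigma, prior = prior,
                 estimate = estimate),
            class = "endo_block")
}

#' @rdname lgm_blocks
#' @export
block_iid <- function(index, n_levels = NULL, sd = 1,
                      prior = pc_prior_iid(), estimate = TRUE) {
  if (is.factor(index)) {
    n_levels <- n_levels %||% nlevels(index)
    index <- as.integer(index)
  } else {
    index <- as.integer(index)
    n_levels <- n_levels %||% max(index)
  }
  A <- Matrix::sparseMatrix(i = seq_along(index), j = index, x = 1,
                            dims = c(length(index), n_levels))
  structure(list(type = "iid", A = A, ncol = n_levels, sd = sd,
                 prior = prior, estimate = estimate),
            class = "endo_block")
}

#' Assemble a latent Gaussian model
#'
#' @param y Response vector: 0/1 for `family = "bernoulli"`, numeric for
#'   `family = "gaussian"` (identity link, known noise sd).
#' @param blocks Named list of [block_fixed()], [block_field()],
#'   [block_iid()] blocks.
#' @param family Observation family.
#' @param gaussian_sd Known observation sd for the Gaussian family.
#' @return Object of class `endo_lgm`.
#' @export
latent_model <- function(y, blocks, family = c("bernoulli", "gaussian"),
                         gaussian_sd = 1) {
  family <- match.arg(family)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    abort("blocks must be a fully named list")
  n <- length(y)
  for (b in blocks)
    if (nrow(b$A) != n) abort("block design rows must match length(y)")
  if (family == "bernoulli" && !all(y %in% c(0, 1)))
    abort("bernoulli response must be 0/1")
  ncols <- vapply(blocks, function(b) b$ncol, integer(1) + 0)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1
  idx <- Map(function(s, e) s:e, starts, ends)
  names(idx) <- names(blocks)
  A <- do.call(cbind, lapply(blocks, function(b) b$A))
  # hyperparameter layout
  tmap <- list(); tinit <- numeric(0); tnames <- character(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (b$type == "field" && isTRUE(b$estimate)) {
      tmap[[length(tmap) + 1]] <- list(block = nm, what = "field")
      tinit <- c(tinit, log(b$range), log(b$sigma))
      tnames <- c(tnames, paste0(nm, ".log_range"), paste0(nm, ".log_sigma"))
    } else if (b$type == "iid" && isTRUE(b$estimate)) {
      tmap[[length(tmap) + 1]] <- list(block = nm, what = "iid")
      tinit <- c(tinit, log(b$sd))
      tnames <- c(tnames, paste0(nm, ".log_sd"))
    }
  }
  names(tinit) <- tnames
  structure(
    list(y = as.numeric(y), A = A, blocks = blocks, idx = idx,
         n = n, p = sum(ncols), family = family, gaussian_sd = gaussian_sd,
         theta_init = tinit, theta_map = tmap),
    class = "endo_lgm"
  )
}

#' @method print endo_lgm
#' @export
print.endo_lgm <- function(x, ...) {
  cat("<endo_lgm> n =", x$n, " latent dim =", x$p,
      " hyperparameters =", length(x$theta_init), "\n")
  for (nm in names(x$blocks))
    cat("  ", nm, " [", x$blocks[[nm]]$type, ", ", x$blocks[[nm]]$ncol,
        "]\n", sep = "")
  invisible(x)
}

# per-block natural-scale hyperparameter values at theta
lgm_hyper_values <- function(model, theta) {
  vals <- list()
  pos <- 1
  theta <- unname(theta)
  for (entry in model$theta_map) {
    if (entry$what == "field") {
      vals[[entry$block]] <- c(range = exp(theta[pos]),
                               sigma = exp(theta[pos + 1]))
      pos <- pos + 2
    } else {
      vals[[entry$block]] <- c(sd = exp(theta[pos]))
      pos <- pos + 1
    }
  }
  vals
}

#' Joint prior precision of the latent vector at hyperparameters theta
#'
#' Block-diagonal over fixed (vague diagonal), field (Matern SPDE precision),
#' and iid (scaled identity) components.
#'
#' @param model [latent_model()] object.
#' @param theta Hyperparameter vector on the log scale (see
#'   `model$theta_init`); missing entries use block initial values.
#' @return Sparse symmetric positive-definite matrix, `model$p` square.
#' @export
lgm_prior_precision <- function(model, theta = model$theta_init) {
  hv <- lgm_hyper_values(model, theta)
  Qs <- lapply(names(model$blocks), function(nm) {
    b <- model$blocks[[nm]]
    if (b$type == "fixed") {
      Matrix::Diagonal(b$ncol, b$prec)
    } else if (b$type == "field") {
      h <- hv[[nm]]
      rng <- if (!is.null(h)) h[["range"]] else b$range
      sg <- if (!is.null(h)) h[["sigma"]] else b$sigma
      matern_precision(b$fem, matern_hyper(rng, sg))
    } else {
      h <- hv[[nm]]
      s <- if (!is.null(h)) h[["sd"]] else b$sd
      Matrix::Diagonal(b$ncol, 1 / s^2)
    }
  })
  Matrix::forceSymmetric(Matrix::bdiag(Qs))
}

# log PC prior of theta including log-scale Jacobians
lgm_theta_logprior <- function(model, theta) {
  hv <- lgm_hyper_values(model, theta)
  lp <- 0
  for (entry in model$theta_map) {
    b <- model$blocks[[entry$block]]
    h <- hv[[entry$block]]
    if (entry$what == "field") {
      lp <- lp + pc_logdens(b$prior, c(h[["range"]], h[["sigma"]])) +
        log(h[["range"]]) + log(h[["sigma"]])
    } else {
      lp <- lp + pc_logdens(b$prior, h[["sd"]]) + log(h[["sd"]])
    }
  }
  lp
}
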