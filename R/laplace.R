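log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# observation negative log-likelihood of linear predictor eta
obs_negloglik <- function(model, eta) {
  if (model$family == "bernoulli") {
    sum(log1pexp(eta) - model$y * eta)
  } else {
    s2 <- model$gaussian_sd^2
    0.5 * model$n * log(2 * pi * s2) + sum((model$y - eta)^2) / (2 * s2)
  }
}

chol_logdet <- function(ch) {
  as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
}

#' Joint negative log posterior of latent vector and hyperparameters
#'
#' Bernoulli (or Gaussian) negative log-likelihood of the logit-linked linear
#' predictor plus the latent Gaussian prior quadratic form and its normalizing
#' constant. Up to the hyperparameter prior, this is the objective whose
#' minimizer over the latent vector is the Laplace mode.
#'
#' @param model [latent_model()] object.
#' @param x Latent vector of length `model$p`.
#' @param theta Hyperparameters (log scale); defaults to block initial values.
#' @return Scalar negative log posterior (constants included).
#' @export
joint_neg_log_posterior <- function(model, x, theta = model$theta_init) {
  if (length(x) != model$p) abort("latent vector has wrong length")
  Q <- lgm_prior_precision(model, theta)
  eta <- as.numeric(model$A %*% x)
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  obs_negloglik(model, eta) +
    0.5 * as.numeric(x %*% (Q %*% x)) -
    0.5 * chol_logdet(ch) + 0.5 * model$p * log(2 * pi)
}

#' Find the Laplace mode of the latent field
#'
#' Damped Newton iteration with sparse Cholesky solves. The returned Gaussian
#' approximation has precision `prior precision + A' W A` with `W` the
#' Bernoulli curvature at the mode (or the constant Gaussian weight).
#'
#' @param model [latent_model()] object.
#' @param theta Hyperparameters (log scale).
#' @param x0 Starting latent vector (zeros by default).
#' @param tol Convergence tolerance on the gradient infinity norm.
#' @param max_iter Maximum Newton iterations.
#' @return List of class `endo_mode`: `mode`, `precision` (sparse), `Q`
#'   (prior precision), `loglik` (observation log-likelihood at mode),
#'   `objective`, `iter`, `converged`, `grad_norm`.
#' @export
find_mode <- function(model, theta = model$theta_init, x0 = NULL,
                      tol = 1e-6, max_iter = 50) {
  Q <- lgm_prior_precision(model, theta)
  A <- model$A
  y <- model$y
  x <- x0 %||% numeric(model$p)
  objective <- function(x, eta) {
    obs_negloglik(model, eta) + 0.5 * as.numeric(x %*% (Q %*% x))
  }
  eta <- as.numeric(A %*% x)
  f <- objective(x, eta)
  converged <- FALSE
  H <- NULL
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    if (model$family == "bernoulli") {
      mu <- plogis(eta)
      w <- mu * (1 - mu)
      resid <- y - mu
    } else {
      w <- rep(1 / model$gaussian_sd^2, model$n)
      resid <- (y - eta) / model$gaussian_sd^2
    }
    g <- as.numeric(Matrix::crossprod(A, resid)) - as.numeric(Q %*% x)
    gnorm <- max(abs(g))
    H <- Matrix::forceSymmetric(
      Q + Matrix::crossprod(A, Matrix::Diagonal(x = w) %*% A))
    if (gnorm <= tol) { converged <- TRUE; break }
    ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
    step <- as.numeric(solve(ch, g, system = "A"))
    alpha <- 1
    repeat {
      x_new <- x + alpha * step
      eta_new <- as.numeric(A %*% x_new)
      f_new <- objective(x_new, eta_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { x_new <- x; eta_new <- eta; f_new <- f; break }
    }
    x <- x_new; eta <- eta_new; f <- f_new
  }
  if (!converged && gnorm > tol * 100)
    warn(paste0("find_mode: gradient norm ", signif(gnorm, 3),
                " after ", max_iter, " iterations"))
  structure(
    list(mode = x, precision = H, Q = Q,
         loglik = -obs_negloglik(model, eta),
         objective = f, iter = it, converged = converged, grad_norm = gnorm,
         theta = theta),
    class = "endo_mode"
  )
}

#' Laplace approximation to the log marginal likelihood
#'
#' `log p(y | theta) ~ loglik(mode) - 1/2 mode' Q mode + 1/2 log|Q|
#' - 1/2 log|H|`, exact for the Gaussian family.
#'
#' @inheritParams find_mode
#' @param mode Optional precomputed [find_mode()] result for this theta.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(model, theta = model$theta_init,
                                    x0 = NULL, mode = NULL) {
  m <- mode %||% find_mode(model, theta, x0 = x0)
  chQ <- Matrix::Cholesky(m$Q, LDL = FALSE, perm = TRUE)
  chH <- Matrix::Cholesky(m$precision, LDL = FALSE, perm = TRUE)
  m$loglik - 0.5 * as.numeric(m$mode %*% (m$Q %*% m$mode)) +
    0.5 * chol_logdet(chQ) - 0.5 * chol_logdet(chH)
}

#' Empirical-Bayes hyperparameter optimization
#'
#' Maximizes the Laplace log marginal likelihood plus the log PC prior over
#' the log-scale hyperparameters with a derivative-free Nelder-Mead simplex,
#' optionally restarted once from a perturbed initial point. Inner Newton
#' solves are warm-started from the previous mode.
#'
#' @param model [latent_model()] object.
#' @param theta_init Initial log-scale hyperparameters.
#' @param maxit Maximum simplex evaluations per start.
#' @param restart Restart once from a perturbed optimum?
#' @param seed Seed for the restart perturbation.
#' @param grid Also build an axis exploration grid around the optimum for
#'   hyperparameter averaging?
#' @param grid_step Log-scale step of the axis grid.
#' @return Object of class `endo_lgm_fit`: the mode fit at the optimum plus
#'   `theta`, `lml`, `log_post`, `opt` diagnostics, the `model`, and
#'   optionally `grid` (tibble of theta points, weights, and mode fits).
#' @export
optimize_hyperparameters <- function(model, theta_init = model$theta_init,
                                     maxit = 150, restart = TRUE, seed = 1,
                                     grid = FALSE, grid_step = 0.7) {
  if (length(theta_init) == 0) {
    return(lgm_fit(model, numeric(0)))
  }
  cache <- new.env()
  cache$x0 <- NULL
  objfun <- function(theta) {
    m <- tryCatch(find_mode(model, theta, x0 = cache$x0),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    cache$x0 <- m$mode
    lml <- tryCatch(log_marginal_likelihood(model, theta, mode = m),
                    error = function(e) NA_real_)
    if (!is.finite(lml)) return(1e10)
    -(lml + lgm_theta_logprior(model, theta))
  }
  run <- function(init) {
    suppressWarnings(
      optim(init, objfun, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-6))
    )
  }
  o1 <- run(theta_init)
  best <- o1
  if (restart) {
    set.seed(seed)
    o2 <- run(o1$par + rnorm(length(o1$par), sd = 0.1))
    if (o2$value < best$value) best <- o2
  }
  theta_hat <- best$par
  names(theta_hat) <- names(model$theta_init)
  fit <- lgm_fit(model, theta_hat)
  fit$opt <- list(value = best$value, counts = best$counts,
                  convergence = best$convergence)
  if (grid) fit$grid <- hyper_grid(model, theta_hat, grid_step)
  fit
}

#' Fit the latent Gaussian model at fixed hyperparameters
#'
#' @inheritParams find_mode
#' @return Object of class `endo_lgm_fit` (see
#'   [optimize_hyperparameters()]).
#' @export
lgm_fit <- function(model, theta = model$theta_init, x0 = NULL) {
  m <- find_mode(model, theta, x0 = x0)
  lml <- log_marginal_likelihood(model, theta, mode = m)
  structure(
    list(model = model, theta = theta, mode = m$mode,
         precision = m$precision, Q = m$Q, loglik = m$loglik, lml = lml,
         log_post = lml + lgm_theta_logprior(model, theta),
         converged = m$converged, iter = m$iter, grad_norm = m$grad_norm,
         hyper = lgm_hyper_values(model, theta)),
    class = "endo_lgm_fit"
  )
}

#' @method print endo_lgm_fit
#' @export
print.endo_lgm_fit <- function(x, ...) {
  cat("<endo_lgm_fit> latent dim =", x$model$p,
      " lml =", signif(x$lml, 6),
      " converged =", x$converged, "\n")
  if (length(x$theta))
    cat("  theta-hat:", paste(names(x$theta), signif(x$theta, 4),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# axis grid around theta_hat with normalized posterior weights
hyper_grid <- function(model, theta_hat, step = 0.7) {
  k <- length(theta_hat)
  pts <- list(theta_hat)
  for (j in seq_len(k)) {
    for (s in c(-step, step)) {
      th <- theta_hat
      th[j] <- th[j] + s
      pts[[length(pts) + 1]] <- th
    }
  }
  fits <- lapply(pts, function(th) {
    tryCatch(lgm_fit(model, th), error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  pts <- pts[keep]; fits <- fits[keep]
  lp <- vapply(fits, function(f) f$log_post, numeric(1))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  tibble(theta = pts, weight = w, fit = fits)
}

#' Sample from the Gaussian approximation of the latent posterior
#'
#' Draws from `N(mode, H^{-1})` at the optimized hyperparameters, or from the
#' mixture over the exploration grid when present.
#'
#' @param fit [lgm_fit()] / [optimize_hyperparameters()] result.
#' @param n_samples Number of draws (>= 2).
#' @param seed Integer seed.
#' @return Matrix, latent dimension x `n_samples`.
#' @export
sample_latent <- function(fit, n_samples = 1000, seed = 1) {
  if (n_samples < 2) abort("n_samples must be >= 2")
  set.seed(seed)
  if (!is.null(fit$grid)) {
    comp <- sample.int(nrow(fit$grid), n_samples, replace = TRUE,
                       prob = fit$grid$weight)
    out <- matrix(0, fit$model$p, n_samples)
    for (g in unique(comp)) {
      cols <- which(comp == g)
      gf <- fit$grid$fit[[g]]
      out[, cols] <- gaussian_draws(gf$mode, gf$precision, length(cols))
    }
    return(out)
  }
  gaussian_draws(fit$mode, fit$precision, n_samples)
}

gaussian_draws <- function(mode, H, n) {
  p <- length(mode)
  ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
  z <- matrix(rnorm(p * n), p, n)
  x <- solve(ch, solve(ch, z, system = "Lt"), system = "Pt")
  as.matrix(x) + mode
}

#' Posterior summaries of linear functionals
#'
#' Applies a sparse linear map to latent posterior samples, optionally
#' transforms (e.g. inverse-logit), and summarizes with the mean and the 2.5,
#' 25, 50, 75, 97.5 percent quantiles (linear interpolation).
#'
#' @param fit [lgm_fit()] result.
#' @param L Linear map (q x latent-dim matrix, dense or sparse).
#' @param transform Function applied elementwise to `L %*% samples`.
#' @param n_samples,seed Sampling controls.
#' @return Tibble with one row per row of `L`: `mean`, `sd`, `q2.5`, `q25`,
#'   `q50`, `q75`, `q97.5`.
#' @export
summarize_functionals <- function(fit, L, transform = identity,
                                  n_samples = 1000, seed = 1) {
  s <- sample_latent(fit, n_samples, seed)
  f <- transform(as.matrix(L %*% s))
  qs <- t(apply(f, 1, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                names = FALSE, type = 7))
  tibble(
    mean = rowMeans(f), sd = apply(f, 1, sd),
    q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3], q75 = qs[, 4],
    q97.5 = qs[, 5]
  )
}
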