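#' Penalized complexity priors
#'
#' PC priors shrink toward the base model (zero variance, infinite range) and
#' are parameterized by tail statements. Three variants are used here:
#'
#' * iid-effect / field standard deviation: `P(sigma > u) = alpha` gives an
#'   exponential density with rate `lambda = -log(alpha) / u`.
#' * Matern range in two dimensions: `P(rho < rho0) = alpha` gives
#'   `pi(rho) = lambda rho^-2 exp(-lambda / rho)` with
#'   `lambda = -log(alpha) * rho0`; its median is `rho0` when `alpha = 0.5`.
#'
#' @param u,alpha Tail threshold and tail probability for sd priors.
#' @param rho0,alpha_rho Range threshold and lower-tail probability.
#' @param sigma0,alpha_sigma Field-sd threshold and upper-tail probability.
#' @return `pc_prior_iid()` / `pc_prior_field()` return prior-spec objects
#'   holding the rates; the `*_logdens` functions return log densities.
#' @name pc_priors
NULL

#' @rdname pc_priors
#' @export
pc_prior_iid <- function(u = 1, alpha = 0.01) {
  stopifnot(u > 0, alpha > 0, alpha < 1)
  structure(list(kind = "iid", u = u, alpha = alpha,
                 lambda = -log(alpha) / u),
            class = "endo_pc_prior")
}

#' @rdname pc_priors
#' @export
pc_prior_field <- function(rho0 = 342, alpha_rho = 0.5,
                           sigma0 = 1, alpha_sigma = 0.01) {
  stopifnot(rho0 > 0, sigma0 > 0,
            alpha_rho > 0, alpha_rho < 1, alpha_sigma > 0, alpha_sigma < 1)
  structure(list(kind = "field", rho0 = rho0, alpha_rho = alpha_rho,
                 sigma0 = sigma0, alpha_sigma = alpha_sigma,
                 lambda_rho = -log(alpha_rho) * rho0,
                 lambda_sigma = -log(alpha_sigma) / sigma0),
            class = "endo_pc_prior")
}

#' @rdname pc_priors
#' @param sigma,rho Positive values at which to evaluate the density.
#' @export
pc_sd_logdens <- function(sigma, u = 1, alpha = 0.01) {
  if (any(sigma <= 0)) abort("sd must be > 0")
  lambda <- -log(alpha) / u
  log(lambda) - lambda * sigma
}

#' @rdname pc_priors
#' @export
pc_range_logdens <- function(rho, rho0 = 342, alpha_rho = 0.5) {
  if (any(rho <= 0)) abort("range must be > 0")
  lambda <- -log(alpha_rho) * rho0
  log(lambda) - 2 * log(rho) - lambda / rho
}

# log prior of an endo_pc_prior at natural-scale value(s); fields take
# c(range, sigma)
pc_logdens <- function(prior, value) {
  if (prior$kind == "iid") {
    pc_sd_logdens(value, prior$u, prior$alpha)
  } else {
    pc_range_logdens(value[1], prior$rho0, prior$alpha_rho) +
      pc_sd_logdens(value[2], prior$sigma0, prior$alpha_sigma)
  }
}
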