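#' Specification of the joint prevalence model
#'
#' Describes which components of the spatially-varying-coefficient logistic
#' model are enabled and how they are shared across host species: per-species
#' global intercept `A_h` and year slope `T_h` (always present, vague
#' Gaussian priors), per-species spatially varying intercept `alpha_h` and
#' slope `tau_h` fields, a residual spatial field `delta` shared across
#' species, and iid collector (`chi`) and scorer (`omega`) effects shared
#' across species.
#'
#' @param year_center,year_scale Centering year and scale divisor for the
#'   year covariate (defaults 1920 and 100, so slopes are per-century logit
#'   changes).
#' @param components Character subset of
#'   `c("alpha", "tau", "delta", "collector", "scorer")`.
#' @param field_prior [pc_prior_field()] for all Matern fields (default:
#'   range median 342 km, sd threshold 1 at 1% tail).
#' @param iid_prior [pc_prior_iid()] for collector/scorer sds (default
#'   `U = 1`, `a = 0.01`).
#' @param range_init,sigma_init,iid_sd_init Initial hyperparameter values.
#' @param share_species_fields If `TRUE`, all species' `alpha` fields share
#'   one set of hyperparameters (one theta pair drives all), likewise `tau`;
#'   default `FALSE` (species-specific hyperparameters).
#' @param fixed_prec Prior precision of the fixed effects (vague default
#'   0.001).
#' @return Object of class `endo_model_spec`.
#' @export
prevalence_model_spec <- function(year_center = 1920, year_scale = 100,
                                  components = c("alpha", "tau", "delta",
                                                 "collector", "scorer"),
                                  field_prior = pc_prior_field(),
                                  iid_prior = pc_prior_iid(),
                                  range_init = 342, sigma_init = 1,
                                  iid_sd_init = 0.5,
                                  share_species_fields = FALSE,
                                  fixed_prec = 1e-3) {
  if (year_scale <= 0) abort("year_scale must be > 0")
  bad <- setdiff(components, c("alpha", "tau", "delta", "collector", "scorer"))
  if (length(bad)) abort(paste("unknown components:", paste(bad, collapse = ", ")))
  structure(
    list(year_center = year_center, year_scale = year_scale,
         components = components, field_prior = field_prior,
         iid_prior = iid_prior, range_init = range_init,
         sigma_init = sigma_init, iid_sd_init = iid_sd_init,
         share_species_fields = share_species_fields,
         fixed_prec = fixed_prec),
    class = "endo_model_spec"
  )
}

#' Assemble the joint-species latent Gaussian model
#'
#' Builds the design and prior-precision structure for the Bernoulli SVC
#' model from a specimen table. The per-record linear predictor is
#' `A_h + T_h yr + alpha_h(l) + tau_h(l) yr + delta(l) + chi_c + omega_s`
#' with `yr = (year - center) / scale`; `delta`, `chi`, `omega` are shared
#' across species.
#'
#' @param specimens Tibble with columns `species`, `year`, `x`, `y`,
#'   `collector_id`, `scorer_id`, and the chosen status column.
#' @param mesh [build_mesh()] mesh covering all record locations.
#' @param spec [prevalence_model_spec()].
#' @param status Which status column drives the response: `"liberal"` (the
#'   headline choice) or `"conservative"`.
#' @return An `endo_lgm` with an `endo_map` attribute locating each model
#'   component in the latent vector.
#' @export
assemble_joint_model <- function(specimens, mesh,
                                 spec = prevalence_model_spec(),
                                 status = c("liberal", "conservative")) {
  status <- match.arg(status)
  status_col <- paste0("status_", status)
  req <- c("species", "year", "x", "y", status_col)
  miss <- setdiff(req, names(specimens))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  specimens <- as_tibble(specimens)
  sp_levels <- sort(unique(specimens$species))
  S <- length(sp_levels)
  spi <- match(specimens$species, sp_levels)
  n <- nrow(specimens)
  yr <- (specimens$year - spec$year_center) / spec$year_scale

  fem <- fem_matrices(mesh)
  P <- mesh_projector(mesh, specimens)
  m <- mesh$n_vertices

  # fixed effects: per-species intercept and slope columns
  Xi <- Matrix::sparseMatrix(i = seq_len(n), j = spi, x = 1, dims = c(n, S))
  Xs <- Matrix::sparseMatrix(i = seq_len(n), j = spi, x = yr, dims = c(n, S))
  X <- cbind(Xi, Xs)
  colnames(X) <- c(paste0("A_", sp_levels), paste0("T_", sp_levels))

  blocks <- list(fixed = block_fixed(X, prec = spec$fixed_prec))

  zero_rows <- function(M, keep) {
    D <- Matrix::Diagonal(n, as.numeric(keep))
    D %*% M
  }
  if ("alpha" %in% spec$components) {
    for (h in seq_len(S)) {
      blocks[[paste0("alpha_", sp_levels[h])]] <- block_field(
        zero_rows(P, spi == h), fem,
        range = spec$range_init, sigma = spec$sigma_init,
        prior = spec$field_prior)
    }
  }
  if ("tau" %in% spec$components) {
    Pyr <- Matrix::Diagonal(n, yr) %*% P
    for (h in seq_len(S)) {
      blocks[[paste0("tau_", sp_levels[h])]] <- block_field(
        zero_rows(Pyr, spi == h), fem,
        range = spec$range_init, sigma = spec$sigma_init,
        prior = spec$field_prior)
    }
  }
  if ("delta" %in% spec$components) {
    blocks$delta <- block_field(P, fem, range = spec$range_init,
                                sigma = spec$sigma_init,
                                prior = spec$field_prior)
  }
  if ("collector" %in% spec$components) {
    if (!"collector_id" %in% names(specimens))
      abort("missing columns: collector_id")
    blocks$collector <- block_iid(factor(specimens$collector_id),
                                  sd = spec$iid_sd_init,
                                  prior = spec$iid_prior)
  }
  if ("scorer" %in% spec$components) {
    if (!"scorer_id" %in% names(specimens))
      abort("missing columns: scorer_id")
    blocks$scorer <- block_iid(factor(specimens$scorer_id),
                               sd = spec$iid_sd_init,
                               prior = spec$iid_prior)
  }

  model <- latent_model(specimens[[status_col]], blocks)
  attr(model, "endo_map") <- list(
    species = sp_levels, mesh = mesh, fem = fem, spec = spec,
    status = status,
    collector_levels = if ("collector" %in% spec$components)
      levels(factor(specimens$collector_id)) else character(0),
    scorer_levels = if ("scorer" %in% spec$components)
      levels(factor(specimens$scorer_id)) else character(0)
  )
  model
}

#' Fit the prevalence model
#'
#' Runs Laplace inference on an assembled model, either optimizing the
#' hyperparameters by empirical Bayes (default) or fixing them at supplied
#' values.
#'
#' @param model [assemble_joint_model()] output.
#' @param optimize Optimize hyperparameters (`TRUE`) or fit at `theta`?
#' @param theta Log-scale hyperparameters used when `optimize = FALSE`
#'   (defaults to the block initial values).
#' @param ... Passed to [optimize_hyperparameters()].
#' @return Object of class `endo_prevalence_fit` wrapping the
#'   `endo_lgm_fit`, the component map, species levels, mesh and spec.
#' @export
fit_prevalence_model <- function(model, optimize = TRUE, theta = NULL, ...) {
  map <- attr(model, "endo_map")
  if (is.null(map)) abort("model must come from assemble_joint_model()")
  fit <- if (optimize) {
    optimize_hyperparameters(model, ...)
  } else {
    lgm_fit(model, theta %||% model$theta_init)
  }
  structure(
    list(fit = fit, map = map, species = map$species, mesh = map$mesh,
         spec = map$spec, model = model),
    class = "endo_prevalence_fit"
  )
}

#' @method print endo_prevalence_fit
#' @export
print.endo_prevalence_fit <- function(x, ...) {
  cat("<endo_prevalence_fit>", length(x$species), "species, latent dim",
      x$model$p, "\n")
  print(tidy(x))
  invisible(x)
}

# latent index of fixed effect; kind in "A" / "T"
fixed_index <- function(fit, kind, species) {
  h <- match(species, fit$species)
  if (is.na(h)) abort(paste("unknown species:", species))
  off <- fit$model$idx$fixed[1] - 1
  off + if (kind == "A") h else length(fit$species) + h
}

#' Tidy fixed-effect summaries of a prevalence fit
#'
#' One row per global intercept `A_h` and slope `T_h` (posterior mean, sd,
#' and 95% interval of the Gaussian approximation).
#'
#' @param x `endo_prevalence_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `species`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.endo_prevalence_fit <- function(x, ...) {
  ids <- x$model$idx$fixed
  V <- marginal_variances(x$fit, ids)
  est <- x$fit$mode[ids]
  se <- sqrt(V)
  S <- length(x$species)
  tibble(
    term = c(rep("intercept", S), rep("slope", S)),
    species = rep(x$species, 2),
    estimate = est, std.error = se,
    conf.low = est - qnorm(0.975) * se,
    conf.high = est + qnorm(0.975) * se
  )
}

#' Glance at a prevalence fit
#'
#' @param x `endo_prevalence_fit`.
#' @param ... Unused.
#' @return One-row tibble: latent dimension, observations, log marginal
#'   likelihood, convergence flag, and optimized hyperparameters (if any) as
#'   a list column.
#' @export
glance.endo_prevalence_fit <- function(x, ...) {
  tibble(
    n = x$model$n, latent_dim = x$model$p,
    log_marginal_likelihood = x$fit$lml,
    converged = x$fit$converged,
    theta = list(x$fit$theta)
  )
}

# marginal posterior variances of selected latent entries (solve per column;
# intended for small index sets such as the fixed effects)
marginal_variances <- function(fit, ids) {
  ch <- Matrix::Cholesky(fit$precision, LDL = FALSE, perm = TRUE)
  vapply(ids, function(j) {
    e <- numeric(fit$model$p)
    e[j] <- 1
    as.numeric(e %*% solve(ch, e, system = "A"))
  }, numeric(1))
}

#' Posterior probability of a positive global year slope
#'
#' Share of posterior samples of `T_h` above zero, the quantity used to state
#' confidence that a species' overall prevalence trend is positive.
#'
#' @param fit `endo_prevalence_fit`.
#' @param species Species label(s); default all.
#' @param n_samples,seed Sampling controls.
#' @return Tibble: `species`, `prob_positive`.
#' @export
probability_positive_global_slope <- function(fit, species = NULL,
                                              n_samples = 1000, seed = 1) {
  species <- species %||% fit$species
  s <- sample_latent(fit$fit, n_samples, seed)
  purrr::map_dfr(species, function(sp) {
    j <- fixed_index(fit, "T", sp)
    tibble(species = sp, prob_positive = mean(s[j, ] > 0))
  })
}

#' Binned observed prevalence through time
#'
#' Exact per-bin proportions of positive statuses; empty bins are omitted.
#'
#' @param specimens Specimen tibble.
#' @param bin_width Bin width in years (> 0).
#' @param status `"liberal"` or `"conservative"`.
#' @return Tibble: `bin_mid`, `n`, `prevalence`.
#' @export
binned_observed_prevalence <- function(specimens, bin_width = 10,
                                       status = "liberal") {
  if (bin_width <= 0) abort("bin_width must be > 0")
  col <- paste0("status_", status)
  specimens %>%
    mutate(bin_mid = floor(.data$year / bin_width) * bin_width +
             bin_width / 2) %>%
    group_by(.data$bin_mid) %>%
    summarise(n = dplyr::n(), prevalence = mean(.data[[col]]),
              .groups = "drop") %>%
    arrange(.data$bin_mid)
}
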