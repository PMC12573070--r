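#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive receives a higher score than a
#' randomly chosen negative, with ties credited one half (the normalized
#' Mann-Whitney U statistic), computed via mid-ranks.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  if (length(labels) != length(scores)) abort("length mismatch")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior predictive check of binned prevalence
#'
#' For each posterior sample, simulates replicated statuses at the observed
#' records (all model components included), bins by year, and reports the
#' per-bin 95% envelope of replicated prevalence together with the fraction
#' of bins whose observed prevalence falls inside it.
#'
#' @param fit `endo_prevalence_fit`.
#' @param specimens The fitted specimen table.
#' @param bin_width Year bin width.
#' @param n_samples,seed Sampling controls.
#' @param status Status column used in the fit.
#' @return List of class `endo_ppc`: `bins` tibble (`bin_mid`, `n`,
#'   `observed`, `rep_lower`, `rep_upper`, `rep_mean`, `inside`) and
#'   `coverage` (fraction of bins inside the envelope).
#' @export
posterior_predictive_check <- function(fit, specimens, bin_width = 10,
                                       n_samples = 200, seed = 1,
                                       status = NULL) {
  status <- status %||% fit$map$status
  col <- paste0("status_", status)
  s <- sample_latent(fit$fit, n_samples, seed)
  eta <- as.matrix(fit$model$A %*% s)
  bins <- floor(specimens$year / bin_width) * bin_width + bin_width / 2
  ub <- sort(unique(bins))
  set.seed(seed + 1)
  yrep <- matrix(rbinom(length(eta), 1, inv_logit(eta)), nrow(eta))
  rep_prev <- apply(yrep, 2, function(col_y) tapply(col_y, bins, mean))
  if (is.null(dim(rep_prev))) rep_prev <- matrix(rep_prev, 1)
  obs <- tapply(specimens[[col]], bins, mean)
  lo <- apply(rep_prev, 1, quantile, 0.025)
  hi <- apply(rep_prev, 1, quantile, 0.975)
  tab <- tibble(
    bin_mid = ub, n = as.integer(table(bins)),
    observed = as.numeric(obs),
    rep_lower = lo, rep_upper = hi, rep_mean = rowMeans(rep_prev),
    inside = obs >= lo & obs <= hi
  )
  structure(list(bins = tab, coverage = mean(tab$inside)),
            class = "endo_ppc")
}

#' @method print endo_ppc
#' @export
print.endo_ppc <- function(x, ...) {
  cat("<endo_ppc>", nrow(x$bins), "bins,",
      sprintf("%.0f%%", 100 * x$coverage), "inside the 95% envelope\n")
  invisible(x)
}

#' Out-of-sample evaluation against contemporary population surveys
#'
#' Predicts prevalence at each survey population's location and year
#' (collector/scorer at zero) and compares to the observed symbiotic
#' fraction: per-population table, plant-level AUC (each population expanded
#' into its Bernoulli records scored by the predicted probability), a
#' logit-logit calibration slope with continuity correction
#' `(y + 0.5) / (n + 1)`, a population-level Spearman rank correlation, and
#' the dispersion contrast (between-population variance of observed vs
#' predicted fractions).
#'
#' @param fit `endo_prevalence_fit`.
#' @param surveys Tibble: `population_id`, `species`, `x`, `y`, `year`,
#'   `n_plants`, `n_symbiotic`. Out-of-hull populations are dropped with a
#'   warning.
#' @param n_samples,seed Sampling controls for prediction bands.
#' @return List of class `endo_oos`: `populations` tibble (with `predicted`
#'   and interval columns), `auc_plant`, `calibration_slope`,
#'   `rank_correlation`, `var_observed`, `var_predicted`.
#' @export
out_of_sample_eval <- function(fit, surveys, n_samples = 1000, seed = 1) {
  if (any(surveys$n_symbiotic > surveys$n_plants) ||
      any(surveys$n_symbiotic < 0))
    abort("n_symbiotic must lie in [0, n_plants]")
  ok <- in_mesh_hull(fit$mesh, surveys)
  if (!all(ok)) {
    warn(paste(sum(!ok), "populations outside the mesh hull were dropped"))
    surveys <- surveys[ok, , drop = FALSE]
  }
  surveys <- arrange(as_tibble(surveys), .data$population_id)
  pred <- purrr::map_dfr(split(surveys, surveys$species), function(d) {
    sp <- d$species[1]
    purrr::map_dfr(split(d, d$year), function(dy) {
      L <- prediction_linear_map(fit, dy, dy$year[1], sp)
      sm <- summarize_functionals(fit$fit, L, transform = inv_logit,
                                  n_samples = n_samples, seed = seed)
      dplyr::bind_cols(dy, rename(sm, predicted = "mean"))
    })
  }) %>% arrange(.data$population_id)
  pred$observed <- pred$n_symbiotic / pred$n_plants
  lab <- rep(rep(c(1, 0), nrow(pred)),
             as.vector(rbind(pred$n_symbiotic,
                             pred$n_plants - pred$n_symbiotic)))
  sc <- rep(pred$predicted, pred$n_plants)
  auc_plant <- if (length(unique(lab)) == 2) auc(lab, sc) else NA_real_
  cc <- (pred$n_symbiotic + 0.5) / (pred$n_plants + 1)
  cal <- unname(coef(lm(logit(cc) ~ logit(pred$predicted)))[2])
  structure(
    list(populations = pred,
         auc_plant = auc_plant,
         calibration_slope = cal,
         rank_correlation = suppressWarnings(
           cor(pred$observed, pred$predicted, method = "spearman")),
         var_observed = var(pred$observed),
         var_predicted = var(pred$predicted)),
    class = "endo_oos"
  )
}

#' @method print endo_oos
#' @export
print.endo_oos <- function(x, ...) {
  cat("<endo_oos>", nrow(x$populations), "populations; plant-level AUC =",
      signif(x$auc_plant, 3), "; calibration slope =",
      signif(x$calibration_slope, 3), "\n")
  invisible(x)
}

#' Spatial sampling-bias robustness experiment
#'
#' Repeats simulate-then-fit at several bias levels (the fraction of records
#' deleted from one spatial region, default the western half of the domain)
#' and scores how well the model recovers the truth: sign recovery of each
#' global slope `T_h`, 95% CI coverage of `A_h` and `T_h`, and the Pearson
#' correlation between the true `tau` surface and the estimated slope
#' surface at a pixel grid.
#'
#' @param config Base [sim_config()]; its `bias_region` defaults to the
#'   western half-plane when unset.
#' @param bias_levels Fractions in `[0, 1)` of records deleted inside the
#'   region.
#' @param n_replicates Replicates per level.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param mesh Optional shared mesh.
#' @param optimize Optimize hyperparameters per fit (slow) or fix at the
#'   generator's values (default).
#' @param n_pixels Pixel grid size for the surface correlation.
#' @return Tibble of class `endo_bias_report`: one row per level x replicate
#'   x species with `sign_match`, `ci_covers_intercept`, `ci_covers_slope`,
#'   `surface_cor`, `fit_ok`; aggregate rows in the `"summary"` attribute.
#' @export
bias_robustness_experiment <- function(config = sim_config(),
                                       bias_levels = c(0, 0.4, 0.8),
                                       n_replicates = 10, seed = 1,
                                       mesh = NULL, optimize = FALSE,
                                       n_pixels = c(12, 8)) {
  if (any(bias_levels < 0 | bias_levels >= 1))
    abort("bias levels must be in [0, 1)")
  if (is.null(config$bias_region)) {
    de <- config$domain_extent
    config$bias_region <- c(de[1], (de[1] + de[2]) / 2, de[3], de[4])
  }
  mesh <- mesh %||% sim_domain_mesh(config)
  de <- config$domain_extent
  pixels <- pixel_grid(de, nx = n_pixels[1], ny = n_pixels[2])
  rows <- list()
  for (li in seq_along(bias_levels)) {
    for (r in seq_len(n_replicates)) {
      rep_seed <- (seed * 1000L + li * 100L + r) %% .Machine$integer.max
      cfg <- config
      cfg$bias_missing_fraction <- bias_levels[li]
      cfg$rng_seed <- rep_seed
      res <- tryCatch({
        sim <- simulate_specimens(cfg, mesh)
        model <- assemble_joint_model(
          sim$specimens, mesh,
          prevalence_model_spec(year_center = cfg$year_center,
                                year_scale = cfg$year_scale,
                                range_init = cfg$field_range,
                                sigma_init = max(cfg$sd_alpha, 0.1)))
        fit <- fit_prevalence_model(model, optimize = optimize,
                                    theta = if (!optimize)
                                      bias_true_theta(model, cfg))
        td <- tidy(fit)
        Ppix <- mesh_projector(mesh, pixels)
        purrr::map_dfr(seq_along(fit$species), function(h) {
          sp <- fit$species[h]
          est <- svc_slope_surface(fit, pixels, species = sp,
                                   n_samples = 300, seed = rep_seed)
          true_tau <- as.numeric(Ppix %*% sim$truth$tau[[h]])
          ti <- filter(td, .data$species == sp)
          tibble(
            bias_level = bias_levels[li], replicate = r, species = sp,
            true_slope = cfg$slope[h],
            est_slope = filter(ti, .data$term == "slope")$estimate,
            sign_match = sign(filter(ti, .data$term == "slope")$estimate) ==
              sign(cfg$slope[h]),
            ci_covers_intercept = dplyr::between(
              cfg$intercept[h],
              filter(ti, .data$term == "intercept")$conf.low,
              filter(ti, .data$term == "intercept")$conf.high),
            ci_covers_slope = dplyr::between(
              cfg$slope[h],
              filter(ti, .data$term == "slope")$conf.low,
              filter(ti, .data$term == "slope")$conf.high),
            surface_cor = suppressWarnings(cor(true_tau, est$mean)),
            fit_ok = TRUE
          )
        })
      }, error = function(e) {
        tibble(bias_level = bias_levels[li], replicate = r,
               species = NA_character_, true_slope = NA_real_,
               est_slope = NA_real_, sign_match = NA,
               ci_covers_intercept = NA, ci_covers_slope = NA,
               surface_cor = NA_real_, fit_ok = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- bind_rows(rows)
  summary <- out %>%
    filter(.data$fit_ok) %>%
    group_by(.data$bias_level) %>%
    summarise(
      sign_recovery = mean(.data$sign_match),
      mean_surface_cor = mean(.data$surface_cor),
      intercept_coverage = mean(.data$ci_covers_intercept),
      slope_coverage = mean(.data$ci_covers_slope),
      n_fits = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summary
  class(out) <- c("endo_bias_report", class(out))
  out
}

# log-scale theta matching the generator's true hyperparameters, in the
# block order of an assembled model
bias_true_theta <- function(model, cfg) {
  th <- model$theta_init
  for (nm in names(th)) {
    if (grepl("^alpha_.*log_sigma$", nm)) th[nm] <- log(max(cfg$sd_alpha, 1e-3))
    if (grepl("^tau_.*log_sigma$", nm)) th[nm] <- log(max(cfg$sd_tau, 1e-3))
    if (grepl("^delta.*log_sigma$", nm)) th[nm] <- log(max(cfg$sd_delta, 1e-3))
    if (grepl("log_range$", nm)) th[nm] <- log(cfg$field_range)
    if (grepl("^collector", nm)) th[nm] <- log(max(cfg$sd_collector, 1e-3))
    if (grepl("^scorer", nm)) th[nm] <- log(max(cfg$sd_scorer, 1e-3))
  }
  th
}

#' @export
autoplot.endo_bias_report <- function(object, ...) {
  s <- attr(object, "summary")
  ggplot2::ggplot(s, ggplot2::aes(factor(.data$bias_level))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$sign_recovery)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_surface_cor),
                        color = "red", size = 3) +
    ggplot2::labs(x = "fraction of records deleted in bias region",
                  y = "sign recovery (bars) / surface correlation (points)")
}
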