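#' Regular pixel grid over an extent
#'
#' Pixel centers of an `nx` by `ny` grid. The defaults approximate the
#' study's prediction resolution (pixels of roughly 60 x 40 km).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param nx,ny Number of pixels per axis; if `NULL`, derived from `dx`,
#'   `dy`.
#' @param dx,dy Pixel dimensions in km (used when `nx`/`ny` are `NULL`).
#' @return Tibble: `pixel_id`, `x`, `y`, `dx`, `dy`.
#' @export
pixel_grid <- function(extent, nx = NULL, ny = NULL, dx = 60, dy = 40) {
  nx <- nx %||% max(1, round((extent[2] - extent[1]) / dx))
  ny <- ny %||% max(1, round((extent[4] - extent[3]) / dy))
  ddx <- (extent[2] - extent[1]) / nx
  ddy <- (extent[4] - extent[3]) / ny
  g <- tidyr::expand_grid(
    x = extent[1] + (seq_len(nx) - 0.5) * ddx,
    y = extent[3] + (seq_len(ny) - 0.5) * ddy
  )
  tibble(pixel_id = seq_len(nrow(g)), x = g$x, y = g$y, dx = ddx, dy = ddy)
}

# sparse linear map from the latent vector to the logit prevalence of one
# species at the given locations/year; collector and scorer effects at zero
prediction_linear_map <- function(fit, locations, year, species) {
  model <- fit$model
  spec <- fit$spec
  h <- match(species, fit$species)
  if (is.na(h)) abort(paste("unknown species:", species))
  q <- nrow(locations)
  yr <- (year - spec$year_center) / spec$year_scale
  P <- mesh_projector(fit$mesh, locations)
  L <- Matrix::Matrix(0, q, model$p, sparse = TRUE)
  L[, fixed_index(fit, "A", species)] <- 1
  L[, fixed_index(fit, "T", species)] <- yr
  nm_a <- paste0("alpha_", species)
  if (nm_a %in% names(model$idx)) L[, model$idx[[nm_a]]] <- P
  nm_t <- paste0("tau_", species)
  if (nm_t %in% names(model$idx)) L[, model$idx[[nm_t]]] <- yr * P
  if ("delta" %in% names(model$idx)) L[, model$idx$delta] <- L[, model$idx$delta] + P
  L
}

drop_outside_hull <- function(fit, pixels) {
  ok <- in_mesh_hull(fit$mesh, pixels)
  if (!all(ok)) {
    warn(paste(sum(!ok), "pixels outside the mesh hull were dropped"))
    pixels <- pixels[ok, , drop = FALSE]
  }
  if (nrow(pixels) == 0) abort("no pixels inside the mesh hull")
  pixels
}

#' Posterior prevalence surface
#'
#' Per-pixel posterior mean and quantiles of predicted prevalence
#' `inverse-logit(A_h + T_h yr + alpha_h + tau_h yr + delta)` for one or more
#' species at a given year. Collector and scorer effects are set to zero (the
#' population-typical specimen).
#'
#' @param fit `endo_prevalence_fit`.
#' @param pixels Pixel tibble ([pixel_grid()]); out-of-hull pixels are
#'   dropped with a warning.
#' @param year Prediction year.
#' @param species Species label(s); default all.
#' @param n_samples,seed Posterior sampling controls.
#' @return Tibble of class `endo_surface`: pixel columns plus `species`,
#'   `year`, `mean`, `sd`, `q2.5` ... `q97.5`.
#' @export
predict_prevalence <- function(fit, pixels, year, species = NULL,
                               n_samples = 1000, seed = 1) {
  species <- species %||% fit$species
  pixels <- drop_outside_hull(fit, pixels)
  out <- purrr::map_dfr(species, function(sp) {
    L <- prediction_linear_map(fit, pixels, year, sp)
    sm <- summarize_functionals(fit$fit, L, transform = inv_logit,
                                n_samples = n_samples, seed = seed)
    dplyr::bind_cols(as_tibble(pixels), species = sp, year = year, sm)
  })
  class(out) <- c("endo_surface", class(out))
  out
}

#' Spatially varying annualized trend surface
#'
#' Per-pixel posterior summaries of the annualized change in prevalence,
#' defined per posterior sample as the probability-scale secant
#' `(P(l, year_to) - P(l, year_from)) / (year_to - year_from)`, then
#' summarized. With the default 1895 to 2020 window this matches the "%
#' change per year" convention used for hotspot/coldspot maps.
#'
#' @param fit `endo_prevalence_fit`.
#' @param pixels Pixel tibble.
#' @param species Species label(s); default all.
#' @param year_from,year_to Secant endpoints.
#' @param n_samples,seed Sampling controls.
#' @return Tibble of class `endo_surface`: pixel columns plus `species`,
#'   `mean`, `sd`, quantiles of the per-year trend (probability scale).
#' @export
svc_slope_surface <- function(fit, pixels, species = NULL,
                              year_from = 1895, year_to = 2020,
                              n_samples = 1000, seed = 1) {
  species <- species %||% fit$species
  pixels <- drop_outside_hull(fit, pixels)
  dy <- year_to - year_from
  out <- purrr::map_dfr(species, function(sp) {
    L0 <- prediction_linear_map(fit, pixels, year_from, sp)
    L1 <- prediction_linear_map(fit, pixels, year_to, sp)
    s <- sample_latent(fit$fit, n_samples, seed)
    slope <- (inv_logit(as.matrix(L1 %*% s)) -
                inv_logit(as.matrix(L0 %*% s))) / dy
    qs <- t(apply(slope, 1, quantile,
                  probs = c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE))
    dplyr::bind_cols(
      as_tibble(pixels), species = sp,
      tibble(mean = rowMeans(slope), sd = apply(slope, 1, sd),
             q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3], q75 = qs[, 4],
             q97.5 = qs[, 5])
    )
  })
  attr(out, "years") <- c(year_from, year_to)
  class(out) <- c("endo_surface", class(out))
  out
}

#' Plot a prevalence or trend surface
#'
#' @param object An `endo_surface` tibble.
#' @param value Column to map to fill.
#' @param ... Unused.
#' @return A ggplot object (tile map faceted by species).
#' @export
autoplot.endo_surface <- function(object, value = "mean", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = value)
}

#' Plot binned observed prevalence with posterior trend bands
#'
#' @param specimens Specimen tibble.
#' @param fit Optional `endo_prevalence_fit` whose global trend curve (fixed
#'   effects only, fields at zero) is overlaid with 50% and 95% bands.
#' @param species Species to plot (default: all in `specimens`).
#' @param bin_width Year bin width.
#' @param status Status column choice.
#' @param n_samples,seed Sampling controls for the bands.
#' @return A ggplot object.
#' @export
plot_prevalence_trend <- function(specimens, fit = NULL, species = NULL,
                                  bin_width = 10, status = "liberal",
                                  n_samples = 1000, seed = 1) {
  species <- species %||% sort(unique(specimens$species))
  binned <- specimens %>%
    filter(.data$species %in% !!species) %>%
    group_by(.data$species) %>%
    dplyr::group_modify(~ binned_observed_prevalence(.x, bin_width, status)) %>%
    ungroup()
  p <- ggplot2::ggplot(binned, ggplot2::aes(.data$bin_mid, .data$prevalence)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "year", y = "observed prevalence")
  if (!is.null(fit)) {
    years <- seq(min(specimens$year), max(specimens$year), by = 5)
    bands <- purrr::map_dfr(species, function(sp) {
      purrr::map_dfr(years, function(yy) {
        yr <- (yy - fit$spec$year_center) / fit$spec$year_scale
        L <- Matrix::Matrix(0, 1, fit$model$p, sparse = TRUE)
        L[1, fixed_index(fit, "A", sp)] <- 1
        L[1, fixed_index(fit, "T", sp)] <- yr
        sm <- summarize_functionals(fit$fit, L, transform = inv_logit,
                                    n_samples = n_samples, seed = seed)
        dplyr::bind_cols(tibble(species = sp, year = yy), sm)
      })
    })
    p <- p +
      ggplot2::geom_ribbon(data = bands,
                           ggplot2::aes(x = .data$year, ymin = .data$q2.5,
                                        ymax = .data$q97.5),
                           inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_ribbon(data = bands,
                           ggplot2::aes(x = .data$year, ymin = .data$q25,
                                        ymax = .data$q75),
                           inherit.aes = FALSE, alpha = 0.3) +
      ggplot2::geom_line(data = bands,
                         ggplot2::aes(x = .data$year, y = .data$mean),
                         inherit.aes = FALSE)
  }
  p
}
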