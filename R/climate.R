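season_months <- list(spring = 1:4, summer = 5:8, autumn = 9:12)

#' Per-year seasonal climate statistics
#'
#' Aggregates monthly pixel values into seasonal statistics using three
#' four-month seasons (spring: Jan-Apr, summer: May-Aug, autumn: Sep-Dec):
#' the seasonal mean for temperature and the seasonal (cumulative) total for
#' precipitation. Pixel-years missing any of a season's four months are
#' excluded with a warning.
#'
#' @param climate Long climate tibble (`pixel_id`, `x`, `y`, `year`,
#'   `month`, `variable`, `value`), e.g. from [simulate_climate()] or
#'   [read_climate()].
#' @return Tibble: `pixel_id`, `x`, `y`, `year`, `season`, `variable`,
#'   `value`.
#' @export
seasonal_values <- function(climate) {
  seas <- tibble(month = 1:12,
                 season = rep(names(season_months), each = 4))
  out <- climate %>%
    left_join(seas, by = "month") %>%
    group_by(.data$pixel_id, .data$x, .data$y, .data$year, .data$season,
             .data$variable) %>%
    summarise(value = if (dplyr::n() == 4) {
      if (.data$variable[1] == "precipitation") sum(.data$value)
      else mean(.data$value)
    } else NA_real_, n_months = dplyr::n(), .groups = "drop")
  if (any(out$n_months != 4)) {
    warn(paste(sum(out$n_months != 4),
               "pixel-year seasons with missing months were excluded"))
    out <- filter(out, .data$n_months == 4)
  }
  select(out, -"n_months")
}

#' 30-year seasonal climate normals
#'
#' Mean and standard deviation (denominator n - 1) of per-year seasonal
#' values over a period, per pixel, season, and variable. The study contrasts
#' the historic (1895-1925) and recent (1990-2020) periods, both endpoints
#' inclusive (31 years). Pixels with fewer than `min_years` complete years
#' are masked (dropped) with a warning.
#'
#' @param seasonal [seasonal_values()] output.
#' @param period `c(first, last)` calendar years, inclusive.
#' @param label Period label stored in the output.
#' @param min_years Completeness threshold.
#' @return Tibble: pixel/season/variable plus `period`, `mean`, `sd`,
#'   `n_years`.
#' @export
climate_normals <- function(seasonal, period, label = NULL, min_years = 25) {
  label <- label %||% paste(period, collapse = "-")
  out <- seasonal %>%
    filter(.data$year >= period[1], .data$year <= period[2]) %>%
    group_by(.data$pixel_id, .data$x, .data$y, .data$season,
             .data$variable) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n_years = dplyr::n(), .groups = "drop") %>%
    mutate(period = label)
  if (any(out$n_years < min_years)) {
    warn(paste(sum(out$n_years < min_years),
               "pixel-season series below the completeness threshold were masked"))
    out <- filter(out, .data$n_years >= min_years)
  }
  out
}

#' Recent-minus-historic climate deltas
#'
#' Computes the twelve climate-change drivers: the change (recent minus
#' historic) in the 30-year mean and sd of each of three seasons x two
#' variables. Driver names follow `"<season>_<variable>_<mean|sd>"`.
#'
#' @param seasonal [seasonal_values()] output covering both periods.
#' @param historic,recent `c(first, last)` year pairs (defaults 1895-1925
#'   and 1990-2020).
#' @param min_years Completeness threshold per period.
#' @return Tibble: `pixel_id`, `x`, `y`, `driver`, `season`, `variable`,
#'   `stat`, `delta`.
#' @export
climate_deltas <- function(seasonal, historic = c(1895, 1925),
                           recent = c(1990, 2020), min_years = 25) {
  hn <- climate_normals(seasonal, historic, "historic", min_years)
  rn <- climate_normals(seasonal, recent, "recent", min_years)
  keys <- c("pixel_id", "x", "y", "season", "variable")
  dplyr::inner_join(
    select(hn, all_of(keys), hist_mean = "mean", hist_sd = "sd"),
    select(rn, all_of(keys), rec_mean = "mean", rec_sd = "sd"),
    by = keys
  ) %>%
    mutate(mean = .data$rec_mean - .data$hist_mean,
           sd = .data$rec_sd - .data$hist_sd) %>%
    select(all_of(keys), "mean", "sd") %>%
    tidyr::pivot_longer(c("mean", "sd"), names_to = "stat",
                        values_to = "delta") %>%
    mutate(driver = paste(.data$season, .data$variable, .data$stat,
                          sep = "_")) %>%
    select("pixel_id", "x", "y", "driver", "season", "variable", "stat",
           "delta")
}

#' Random pixel subsample
#'
#' Uniform sampling of pixels without replacement, used to avoid inflated
#' confidence from regressing on arbitrarily many prediction pixels (the
#' study uses 250).
#'
#' @param pixels Tibble with a `pixel_id` column.
#' @param n Subsample size.
#' @param seed Integer seed.
#' @return The subsampled rows, in original order.
#' @export
subsample_pixels <- function(pixels, n = 250, seed = 1) {
  ids <- unique(pixels$pixel_id)
  if (n > length(ids)) abort("n exceeds the number of available pixels")
  set.seed(seed)
  keep <- sample(ids, n)
  filter(pixels, .data$pixel_id %in% keep)
}

#' Post-hoc regression of fitted trends on climate-change drivers
#'
#' Regresses the annualized prevalence trend (posterior mean of the SVC slope
#' surface, expressed in % per year) on each climate delta with Gaussian
#' errors: one simple regression per driver (default, matching the marginal
#' presentation) or one joint multiple regression. Sign probabilities are the
#' t-distribution tail areas of the OLS slope (identical to a flat-prior
#' Bayesian reading). Units: temperature drivers per degree C; precipitation
#' drivers per 100 mm.
#'
#' @param slopes SVC slope surface tibble ([svc_slope_surface()]) for one
#'   species, with `pixel_id` and `mean` (per-year probability change).
#' @param deltas [climate_deltas()] output aligned on `pixel_id`.
#' @param drivers Driver names to use (default: all in `deltas`).
#' @param mode `"per-driver"` or `"joint"`.
#' @return Tibble of class `endo_climreg`: per driver `slope`, `intercept`
#'   (joint mode: common intercept), `std.error`, `residual_sd`,
#'   `prob_positive`, `prob_negative`, `n_pixels`, `unit`.
#' @export
posthoc_regression <- function(slopes, deltas, drivers = NULL,
                               mode = c("per-driver", "joint")) {
  mode <- match.arg(mode)
  drivers <- drivers %||% sort(unique(deltas$driver))
  wide <- deltas %>%
    filter(.data$driver %in% drivers) %>%
    mutate(delta = ifelse(.data$variable == "precipitation",
                          .data$delta / 100, .data$delta)) %>%
    select("pixel_id", "driver", "delta") %>%
    tidyr::pivot_wider(names_from = "driver", values_from = "delta")
  df <- slopes %>%
    mutate(trend_pct = 100 * .data$mean) %>%
    select("pixel_id", "trend_pct") %>%
    dplyr::inner_join(wide, by = "pixel_id")
  if (nrow(df) < length(drivers) + 2)
    abort("too few aligned pixels for regression")
  for (d in drivers) {
    if (sd(df[[d]]) == 0)
      abort(paste("constant covariate, singular design:", d))
  }
  unit_of <- function(d) if (grepl("precipitation", d)) "per 100 mm"
  else "per degree C"
  res <- if (mode == "per-driver") {
    purrr::map_dfr(drivers, function(d) {
      m <- lm(df$trend_pct ~ df[[d]])
      sm <- summary(m)
      est <- sm$coefficients[2, 1]
      se <- sm$coefficients[2, 2]
      tt <- est / se
      dfree <- m$df.residual
      tibble(driver = d, slope = est, intercept = coef(m)[1],
             std.error = se, residual_sd = sm$sigma,
             prob_positive = pt(tt, dfree),
             prob_negative = 1 - pt(tt, dfree),
             n_pixels = nrow(df), unit = unit_of(d))
    })
  } else {
    m <- lm(stats::reformulate(sprintf("`%s`", drivers), "trend_pct"),
            data = df)
    sm <- summary(m)
    purrr::map_dfr(drivers, function(d) {
      est <- sm$coefficients[d, 1]
      se <- sm$coefficients[d, 2]
      tt <- est / se
      tibble(driver = d, slope = est, intercept = coef(m)[1],
             std.error = se, residual_sd = sm$sigma,
             prob_positive = pt(tt, m$df.residual),
             prob_negative = 1 - pt(tt, m$df.residual),
             n_pixels = nrow(df), unit = unit_of(d))
    })
  }
  class(res) <- c("endo_climreg", class(res))
  res
}

#' Plot post-hoc climate regression results
#'
#' @param object `endo_climreg` tibble.
#' @param ... Unused.
#' @return ggplot: slope estimates with approximate 95% intervals per driver.
#' @export
autoplot.endo_climreg <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$slope, .data$driver)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$slope - 1.96 * .data$std.error,
                   xmax = .data$slope + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::labs(x = "trend change (% per year per driver unit)",
                  y = NULL)
}
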