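#' Simulation configuration for synthetic herbarium data
#'
#' Defines the study conditions emulated by the generator: a rectangular
#' domain in km, per-species global intercepts and slopes on the logit scale
#' (slope per scaled-year unit, i.e. per century with the default year
#' scaling), Matern fields for the spatially varying intercept, slope, and
#' shared residual field, iid collector and scorer effects, paired
#' liberal/conservative scoring with one-way demotion, and optional spatial
#' thinning of records in a bias region.
#'
#' Defaults mirror the herbarium study scale: three host species of roughly
#' 780 specimens each collected 1824-2019, prevalence rising from about
#' 25-40% to 50-75% over the record (global logit slopes of +0.8 to +1.8 per
#' century), a 342 km field range, 50 collectors, 25 scorers, and an 11%
#' demotion rate reproducing 89% liberal/conservative agreement.
#'
#' @param domain_extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param n_species Number of host species.
#' @param n_specimens_per_species Specimens per species (before bias
#'   thinning).
#' @param year_range `c(start, end)` calendar years.
#' @param temporal_weighting Power-law exponent for sampling years: weight
#'   proportional to `(year - start + 1)^(temporal_weighting - 1)`; 1 =
#'   uniform, larger skews toward recent years.
#' @param intercept,slope Per-species true `A_h` (logit at the centering
#'   year) and `T_h` (logit change per scaled-year unit); recycled to
#'   `n_species`.
#' @param year_center,year_scale Year centering/scaling used when forming the
#'   linear predictor (defaults 1920 and 100: slopes are per century).
#' @param field_range Matern range (km) shared by the true fields.
#' @param sd_alpha,sd_tau,sd_delta Marginal sds of the spatially varying
#'   intercept fields, slope fields, and the shared residual field.
#' @param n_collectors,n_scorers Numbers of iid effect levels.
#' @param sd_collector,sd_scorer iid effect sds (logit scale).
#' @param conservative_mismatch_rate Probability a liberal positive is
#'   demoted to a conservative negative.
#' @param bias_region `NULL`, or `c(xmin, xmax, ymin, ymax)` (use `-Inf` /
#'   `Inf` for a half-plane) within which records are thinned.
#' @param bias_missing_fraction Probability a record inside `bias_region` is
#'   deleted.
#' @param seeds_scored_range Inclusive range of seeds scored per specimen.
#' @param rng_seed Integer seed.
#' @return Validated list of class `endo_sim_config`.
#' @export
sim_config <- function(domain_extent = c(0, 1500, 0, 1000),
                       n_species = 3,
                       n_specimens_per_species = 780,
                       year_range = c(1824, 2019),
                       temporal_weighting = 1,
                       intercept = c(-0.85, -0.2, 0),
                       slope = c(1.8, 1.2, 0.8),
                       year_center = 1920, year_scale = 100,
                       field_range = 342,
                       sd_alpha = 1, sd_tau = 0.5, sd_delta = 0.5,
                       n_collectors = 50, n_scorers = 25,
                       sd_collector = 0.25, sd_scorer = 0.5,
                       conservative_mismatch_rate = 0.11,
                       bias_region = NULL, bias_missing_fraction = 0,
                       seeds_scored_range = c(5, 10),
                       rng_seed = 1) {
  cfg <- list(domain_extent = domain_extent, n_species = n_species,
              n_specimens_per_species = n_specimens_per_species,
              year_range = year_range,
              temporal_weighting = temporal_weighting,
              intercept = rep_len(intercept, n_species),
              slope = rep_len(slope, n_species),
              year_center = year_center, year_scale = year_scale,
              field_range = field_range, sd_alpha = sd_alpha,
              sd_tau = sd_tau, sd_delta = sd_delta,
              n_collectors = n_collectors, n_scorers = n_scorers,
              sd_collector = sd_collector, sd_scorer = sd_scorer,
              conservative_mismatch_rate = conservative_mismatch_rate,
              bias_region = bias_region,
              bias_missing_fraction = bias_missing_fraction,
              seeds_scored_range = seeds_scored_range,
              rng_seed = rng_seed)
  validate_sim_config(cfg)
  structure(cfg, class = "endo_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(domain_extent) != 4 || domain_extent[2] <= domain_extent[1] ||
        domain_extent[4] <= domain_extent[3])
      abort("domain_extent must be c(xmin, xmax, ymin, ymax) with positive extent")
    if (year_range[1] >= year_range[2]) abort("year_range start must be < end")
    if (conservative_mismatch_rate < 0 || conservative_mismatch_rate > 1)
      abort("conservative_mismatch_rate must be in [0, 1]")
    if (bias_missing_fraction < 0 || bias_missing_fraction > 1)
      abort("bias_missing_fraction must be in [0, 1]")
    if (field_range <= 0) abort("field_range must be > 0")
    if (any(c(sd_alpha, sd_tau, sd_delta, sd_collector, sd_scorer) < 0))
      abort("sds must be >= 0")
    if (year_scale <= 0) abort("year_scale must be > 0")
    if (temporal_weighting <= 0) abort("temporal_weighting must be > 0")
  })
  invisible(cfg)
}

#' Default mesh over a simulation domain
#'
#' Convenience wrapper building a mesh from the domain corners.
#'
#' @param config [sim_config()] object.
#' @param max_edge,extension,cutoff Passed to [build_mesh()].
#' @return An `endo_mesh`.
#' @export
sim_domain_mesh <- function(config, max_edge = 200, extension = 300,
                            cutoff = 1) {
  de <- config$domain_extent
  corners <- expand.grid(x = de[1:2], y = de[3:4])
  build_mesh(corners, cutoff = cutoff, max_edge = max_edge,
             extension = extension)
}

in_region <- function(x, y, region) {
  if (is.null(region)) return(rep(FALSE, length(x)))
  x >= region[1] & x <= region[2] & y >= region[3] & y <= region[4]
}

#' Simulate herbarium specimen records from the prevalence model
#'
#' Draws collection locations uniformly over the domain (then thins inside
#' the bias region), collection years with a configurable recency weighting,
#' and binary endophyte statuses from the Bernoulli model: logit prevalence =
#' `A_h + T_h yr + alpha_h(l) + tau_h(l) yr + delta(l) + chi_c + omega_s`
#' with true Matern fields and iid effects. Conservative scores are produced
#' by one-way demotion of liberal positives.
#'
#' @param config [sim_config()] object.
#' @param mesh Optional mesh; defaults to [sim_domain_mesh()].
#' @return List of class `endo_sim`: `specimens` (tibble of records),
#'   `truth` (fixed effects, node values of all fields, iid effects),
#'   `mesh`, `config`.
#' @export
simulate_specimens <- function(config, mesh = NULL) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  mesh <- mesh %||% sim_domain_mesh(config)
  fem <- fem_matrices(mesh)
  S <- config$n_species
  de <- config$domain_extent

  species <- paste0("species_", seq_len(S))
  alpha <- lapply(seq_len(S), function(h)
    sample_gp_field(mesh, config$field_range, config$sd_alpha, fem = fem))
  tau <- lapply(seq_len(S), function(h)
    sample_gp_field(mesh, config$field_range, config$sd_tau, fem = fem))
  delta <- sample_gp_field(mesh, config$field_range, config$sd_delta,
                           fem = fem)
  chi <- rnorm(config$n_collectors, 0, config$sd_collector)
  omega <- rnorm(config$n_scorers, 0, config$sd_scorer)

  n_tot <- S * config$n_specimens_per_species
  yrs <- config$year_range[1]:config$year_range[2]
  wt <- (yrs - config$year_range[1] + 1)^(config$temporal_weighting - 1)

  rec <- tibble(
    species = rep(species, each = config$n_specimens_per_species),
    species_i = rep(seq_len(S), each = config$n_specimens_per_species),
    year = sample(yrs, n_tot, replace = TRUE, prob = wt),
    x = runif(n_tot, de[1], de[2]),
    y = runif(n_tot, de[3], de[4]),
    collector_id = paste0("c", sample.int(config$n_collectors, n_tot,
                                          replace = TRUE)),
    scorer_id = paste0("s", sample.int(config$n_scorers, n_tot,
                                       replace = TRUE)),
    seeds_scored = sample(config$seeds_scored_range[1]:
                            config$seeds_scored_range[2],
                          n_tot, replace = TRUE)
  )

  # spatial bias: delete records inside the bias region with given probability
  if (!is.null(config$bias_region) && config$bias_missing_fraction > 0) {
    inside <- in_region(rec$x, rec$y, config$bias_region)
    drop <- inside & (runif(n_tot) < config$bias_missing_fraction)
    rec <- rec[!drop, ]
    if (nrow(rec) == 0) abort("no records remain after bias thinning")
  }

  P <- mesh_projector(mesh, rec)
  yr <- (rec$year - config$year_center) / config$year_scale
  ci <- as.integer(sub("^c", "", rec$collector_id))
  si <- as.integer(sub("^s", "", rec$scorer_id))
  eta <- config$intercept[rec$species_i] + config$slope[rec$species_i] * yr +
    chi[ci] + omega[si]
  for (h in seq_len(S)) {
    rows <- rec$species_i == h
    eta[rows] <- eta[rows] +
      as.numeric(P[rows, , drop = FALSE] %*% alpha[[h]]) +
      yr[rows] * as.numeric(P[rows, , drop = FALSE] %*% tau[[h]])
  }
  eta <- eta + as.numeric(P %*% delta)

  prob <- inv_logit(eta)
  rec$status_liberal <- rbinom(nrow(rec), 1, prob)
  demote <- rec$status_liberal == 1 &
    runif(nrow(rec)) < config$conservative_mismatch_rate
  rec$status_conservative <- ifelse(demote, 0L, rec$status_liberal)
  rec$true_prob <- prob
  rec$species_i <- NULL

  structure(
    list(specimens = rec,
         truth = list(intercept = config$intercept, slope = config$slope,
                      alpha = alpha, tau = tau, delta = delta,
                      chi = chi, omega = omega, species = species),
         mesh = mesh, config = config),
    class = "endo_sim"
  )
}

#' @method print endo_sim
#' @export
print.endo_sim <- function(x, ...) {
  cat("<endo_sim>", nrow(x$specimens), "specimens,",
      x$config$n_species, "species, years",
      paste(x$config$year_range, collapse = "-"), "\n")
  invisible(x)
}

#' Simulate monthly climate grids
#'
#' Monthly temperature and precipitation on a pixel grid:
#' `value = baseline + trend (year - first) / 100 + amplitude *
#' cos(2 pi (month - peak) / 12) + noise`; precipitation is truncated at 0.
#'
#' @param pixels Tibble with `pixel_id`, `x`, `y` (e.g. from
#'   [pixel_grid()]), or `NULL` to build an `nx` by `ny` grid over `extent`.
#' @param years Calendar years covered (default 1895:2020).
#' @param nx,ny,extent Grid spec used when `pixels` is `NULL`.
#' @param temp_baseline,temp_trend,temp_amp,temp_noise_sd Temperature
#'   parameters: baseline deg C, secular trend per century, seasonal
#'   amplitude, iid noise sd.
#' @param precip_baseline,precip_trend,precip_amp,precip_noise_sd Monthly
#'   precipitation parameters (mm).
#' @param seed Integer seed.
#' @return Long tibble: `pixel_id`, `x`, `y`, `year`, `month`, `variable`
#'   (temperature/precipitation), `value`.
#' @export
simulate_climate <- function(pixels = NULL, years = 1895:2020,
                             nx = 10, ny = 8,
                             extent = c(0, 1500, 0, 1000),
                             temp_baseline = 15, temp_trend = 1,
                             temp_amp = 10, temp_noise_sd = 1,
                             precip_baseline = 80, precip_trend = 20,
                             precip_amp = 30, precip_noise_sd = 15,
                             seed = 1) {
  set.seed(seed)
  if (is.null(pixels)) {
    pixels <- pixel_grid(extent, nx = nx, ny = ny)
  }
  if (nrow(pixels) == 0) abort("empty pixel grid")
  base <- tidyr::expand_grid(
    pixels[, c("pixel_id", "x", "y")],
    year = years, month = 1:12
  )
  t0 <- min(years)
  n <- nrow(base)
  temp <- base %>%
    mutate(variable = "temperature",
           value = temp_baseline + temp_trend * (.data$year - t0) / 100 +
             temp_amp * cos(2 * pi * (.data$month - 7) / 12) +
             rnorm(n, 0, temp_noise_sd))
  prec <- base %>%
    mutate(variable = "precipitation",
           value = pmax(0, precip_baseline +
                          precip_trend * (.data$year - t0) / 100 +
                          precip_amp * cos(2 * pi * (.data$month - 7) / 12) +
                          rnorm(n, 0, precip_noise_sd)))
  bind_rows(temp, prec)
}

#' Simulate contemporary population surveys from simulation truth
#'
#' Places survey populations uniformly over the domain and draws the number
#' of symbiotic plants per population as Binomial(n, P) with P the true
#' prevalence at the population's location and year (collector/scorer effects
#' at zero, the population-typical specimen).
#'
#' @param sim [simulate_specimens()] output.
#' @param n_populations,plants_per_population Survey scale; defaults emulate
#'   the study's 63 populations of about 23 plants.
#' @param year Survey calendar year.
#' @param species Species surveyed (defaults to the first).
#' @param seed Integer seed.
#' @return Tibble: `population_id`, `species`, `x`, `y`, `year`, `n_plants`,
#'   `n_symbiotic`, `true_prob`.
#' @export
simulate_surveys <- function(sim, n_populations = 63,
                             plants_per_population = 23,
                             year = 2015, species = NULL, seed = 1) {
  cfg <- sim$config
  if (year < cfg$year_range[1] - 10 || year > cfg$year_range[2] + 10)
    abort("survey year must be within or adjacent to the simulated year range")
  set.seed(seed)
  species <- species %||% sim$truth$species[1]
  h <- match(species, sim$truth$species)
  if (is.na(h)) abort("unknown species")
  de <- cfg$domain_extent
  pop <- tibble(
    population_id = paste0("pop_", seq_len(n_populations)),
    species = species,
    x = runif(n_populations, de[1], de[2]),
    y = runif(n_populations, de[3], de[4]),
    year = year,
    n_plants = plants_per_population
  )
  P <- mesh_projector(sim$mesh, pop)
  yr <- (year - cfg$year_center) / cfg$year_scale
  eta <- cfg$intercept[h] + cfg$slope[h] * yr +
    as.numeric(P %*% sim$truth$alpha[[h]]) +
    yr * as.numeric(P %*% sim$truth$tau[[h]]) +
    as.numeric(P %*% sim$truth$delta)
  pop$true_prob <- inv_logit(eta)
  pop$n_symbiotic <- rbinom(n_populations, pop$n_plants, pop$true_prob)
  pop
}
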