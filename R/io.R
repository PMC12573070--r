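#' Read and validate a specimen table
#'
#' Reads a CSV of herbarium specimen records, validates each row (parseable
#' year and coordinates, binary statuses, conservative <= liberal, seeds >=
#' 1), projects lon/lat to km, and returns the clean records; rejected rows
#' and their reasons are attached as the `"rejects"` attribute and reported.
#'
#' @param path CSV path. Lines starting with `#` are treated as comments.
#'   Expected columns: `species`, `year`, `lon`, `lat`, `collector_id`,
#'   `scorer_id`, `status_liberal`, `status_conservative`, and optionally
#'   `seeds_scored` (defaults to 1).
#' @param col_map Optional named character vector mapping expected names to
#'   the file's column names, e.g. `c(lon = "longitude")`.
#' @param origin Optional projection origin `c(lon, lat)`.
#' @return Tibble of validated records with `x`, `y` in km; attributes
#'   `"rejects"` (tibble with a `reason` column) and `"proj_origin"`.
#' @export
read_specimens <- function(path, col_map = NULL, origin = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw))
        abort(paste("mapped column not in file:", col_map[[nm]]))
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  req <- c("species", "year", "lon", "lat", "collector_id", "scorer_id",
           "status_liberal", "status_conservative")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    abort(paste("missing required columns:", paste(miss, collapse = ", ")))
  if (!"seeds_scored" %in% names(raw)) raw$seeds_scored <- "1"

  num <- function(v) suppressWarnings(as.numeric(v))
  parsed <- raw %>%
    mutate(year_n = num(.data$year), lon_n = num(.data$lon),
           lat_n = num(.data$lat),
           lib = num(.data$status_liberal),
           con = num(.data$status_conservative),
           seeds = num(.data$seeds_scored))
  reason <- dplyr::case_when(
    is.na(parsed$year_n) | parsed$year_n != floor(parsed$year_n) ~
      "unparseable year",
    is.na(parsed$lon_n) | is.na(parsed$lat_n) ~ "unparseable coordinates",
    !(parsed$lib %in% c(0, 1)) | !(parsed$con %in% c(0, 1)) ~
      "non-binary status",
    parsed$con > parsed$lib ~ "conservative exceeds liberal",
    is.na(parsed$seeds) | parsed$seeds < 1 ~ "seeds_scored below 1",
    TRUE ~ NA_character_
  )
  rejects <- dplyr::bind_cols(raw[!is.na(reason), ],
                              tibble(reason = reason[!is.na(reason)]))
  ok <- parsed[is.na(reason), ]
  out <- tibble(
    species = ok$species, year = as.integer(ok$year_n),
    lon = ok$lon_n, lat = ok$lat_n,
    collector_id = ok$collector_id, scorer_id = ok$scorer_id,
    status_liberal = as.integer(ok$lib),
    status_conservative = as.integer(ok$con),
    seeds_scored = as.integer(ok$seeds)
  )
  out <- project_lonlat(out, origin)
  if (nrow(rejects))
    inform(paste(nrow(rejects), "rows rejected; see attr(x, 'rejects')"))
  attr(out, "rejects") <- rejects
  out
}

#' Read a contemporary survey table
#'
#' @param path CSV with columns `population_id`, `species`, `lon`, `lat`
#'   (or `x`, `y` in km), `year`, `n_plants`, `n_symbiotic`.
#' @param origin Optional projection origin for lon/lat files.
#' @return Tibble; empty files yield an empty tibble with a warning.
#' @export
read_surveys <- function(path, origin = NULL) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (nrow(d) == 0) {
    warn("empty survey file")
    return(as_tibble(d))
  }
  if (!all(c("x", "y") %in% names(d))) d <- project_lonlat(d, origin)
  if (any(d$n_symbiotic > d$n_plants | d$n_symbiotic < 0))
    abort("n_symbiotic must lie in [0, n_plants]")
  as_tibble(d)
}

#' Read a long-format climate grid CSV
#'
#' Columns `pixel_id`, `x`, `y`, `year`, `month`, `variable`, `value`; rows
#' are reordered by (pixel, variable, year, month) so on-disk permutations do
#' not matter.
#'
#' @param path CSV path.
#' @return Long climate tibble.
#' @export
read_climate <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("pixel_id", "x", "y", "year", "month", "variable", "value")
  miss <- setdiff(req, names(d))
  if (length(miss))
    abort(paste("missing climate columns:", paste(miss, collapse = ", ")))
  arrange(as_tibble(d), .data$pixel_id, .data$variable, .data$year,
          .data$month)
}

provenance_header <- function(stage, config_hash = "none") {
  c(paste0("# endotrend v", as.character(utils::packageVersion("endotrend"))),
    paste0("# stage: ", stage),
    paste0("# config_hash: ", config_hash))
}

#' Write a tibble as CSV with a provenance header
#'
#' Floats are written at 12 significant digits so write/read round trips are
#' faithful to about 1e-9 relative error.
#'
#' @param data Tibble (surface, report, regression table, ...).
#' @param path Output CSV path.
#' @param stage Stage label recorded in the header.
#' @param config_hash Provenance hash recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(data, path, stage = "report",
                         config_hash = "none") {
  num <- vapply(data, is.double, logical(1))
  out <- as.data.frame(data)
  out[num] <- lapply(out[num], function(v) signif(v, 12))
  writeLines(provenance_header(stage, config_hash), path)
  suppressWarnings(
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double",
                       append = TRUE, quote = TRUE)
  )
  invisible(path)
}

#' @rdname write_report
#' @export
write_surface <- function(data, path, stage = "surface",
                          config_hash = "none") {
  write_report(data, path, stage = stage, config_hash = config_hash)
}

#' Run the full analysis pipeline on synthetic or file inputs
#'
#' Executes the stages fit, predict, slopes, climate, regress, and validate
#' in order, writing one CSV per stage plus a manifest into `out_dir`.
#' Reruns skip stages whose manifest hash matches the current configuration
#' unless `force = TRUE`.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `specimens` (CSV path) or `simulation` (list of [sim_config()]
#'   arguments), optional `climate` (CSV path) or `climate_sim` (list of
#'   [simulate_climate()] arguments), optional `surveys` (CSV path),
#'   `status` ("liberal"/"conservative"), `mesh` (list: cutoff, max_edge,
#'   extension), `optimize` (logical), `n_subsample_pixels`, `pixel` (list:
#'   nx, ny), `years` (list: from, to), `seed`.
#' @param out_dir Output directory (created if needed).
#' @param force Recompute all stages even if manifests match.
#' @return Invisible list of stage outputs.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  cfg_hash <- rlang::hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path) && !force)
    jsonlite::read_json(manifest_path) else list()
  done <- function(stage, file) {
    identical(manifest[[stage]], cfg_hash) &&
      file.exists(file.path(out_dir, file))
  }
  mark <- function(stage) {
    manifest[[stage]] <<- cfg_hash
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  results <- list()

  # inputs
  if (!is.null(config$specimens)) {
    specimens <- read_specimens(config$specimens)
  } else {
    sim <- do.call(sim_config, config$simulation %||% list())
    simres <- simulate_specimens(sim)
    specimens <- simres$specimens
  }
  mesh_args <- config$mesh %||% list()
  mesh <- do.call(build_mesh, c(list(points = specimens), mesh_args))

  status <- config$status %||% "liberal"

  # fit
  if (done("fit", "fixed_effects.csv")) {
    inform("fit: up to date, skipping")
    fit <- readRDS(file.path(out_dir, "fit.rds"))
  } else {
    model <- assemble_joint_model(specimens, mesh, status = status)
    fit <- fit_prevalence_model(model,
                                optimize = isTRUE(config$optimize),
                                seed = seed)
    saveRDS(fit, file.path(out_dir, "fit.rds"))
    write_report(tidy(fit), file.path(out_dir, "fixed_effects.csv"),
                 "fit", cfg_hash)
    mark("fit")
  }
  results$fit <- fit

  ext <- c(min(specimens$x), max(specimens$x),
           min(specimens$y), max(specimens$y))
  pix_args <- config$pixel %||% list()
  pixels <- do.call(pixel_grid, c(list(extent = ext), pix_args))
  pixels <- pixels[in_mesh_hull(mesh, pixels), ]
  yr_from <- config$years$from %||% 1895
  yr_to <- config$years$to %||% 2020

  if (done("predict", "prevalence_surface.csv")) {
    inform("predict: up to date, skipping")
    surf <- read_climate_agnostic(file.path(out_dir, "prevalence_surface.csv"))
  } else {
    surf <- bind_rows(
      predict_prevalence(fit, pixels, yr_from, seed = seed),
      predict_prevalence(fit, pixels, yr_to, seed = seed))
    write_surface(surf, file.path(out_dir, "prevalence_surface.csv"),
                  "predict", cfg_hash)
    mark("predict")
  }
  results$surface <- surf

  if (done("slopes", "slope_surface.csv")) {
    inform("slopes: up to date, skipping")
    slopes <- read_climate_agnostic(file.path(out_dir, "slope_surface.csv"))
  } else {
    slopes <- svc_slope_surface(fit, pixels, year_from = yr_from,
                                year_to = yr_to, seed = seed)
    write_surface(slopes, file.path(out_dir, "slope_surface.csv"),
                  "slopes", cfg_hash)
    mark("slopes")
  }
  results$slopes <- slopes

  # climate + regression
  climate <- if (!is.null(config$climate)) {
    read_climate(config$climate)
  } else {
    do.call(simulate_climate,
            modifyList(list(pixels = pixels, seed = seed),
                       config$climate_sim %||% list()))
  }
  if (done("regress", "climate_regression.csv")) {
    inform("regress: up to date, skipping")
    reg <- read_climate_agnostic(file.path(out_dir, "climate_regression.csv"))
  } else {
    deltas <- climate_deltas(seasonal_values(climate))
    n_sub <- min(config$n_subsample_pixels %||% 250,
                 dplyr::n_distinct(pixels$pixel_id))
    sub <- subsample_pixels(pixels, n_sub, seed = seed)
    reg <- purrr::map_dfr(fit$species, function(sp) {
      sl <- filter(slopes, .data$species == sp,
                   .data$pixel_id %in% sub$pixel_id)
      mutate(posthoc_regression(sl, deltas), species = sp)
    })
    write_report(reg, file.path(out_dir, "climate_regression.csv"),
                 "regress", cfg_hash)
    mark("regress")
  }
  results$regression <- reg

  # validate
  if (!done("validate", "validation.csv")) {
    ppc <- posterior_predictive_check(fit, specimens, seed = seed)
    scores <- as.numeric(fit$model$A %*% fit$fit$mode)
    metrics <- tibble(
      metric = c("auc_in_sample", "ppc_coverage"),
      value = c(auc(fit$model$y, scores), ppc$coverage))
    if (!is.null(config$surveys)) {
      oos <- out_of_sample_eval(fit, read_surveys(config$surveys),
                                seed = seed)
      metrics <- bind_rows(metrics, tibble(
        metric = c("auc_out_of_sample_plant", "calibration_slope"),
        value = c(oos$auc_plant, oos$calibration_slope)))
    }
    write_report(metrics, file.path(out_dir, "validation.csv"),
                 "validate", cfg_hash)
    mark("validate")
    results$validation <- metrics
  } else {
    inform("validate: up to date, skipping")
    results$validation <- read_climate_agnostic(
      file.path(out_dir, "validation.csv"))
  }
  invisible(results)
}

# read back any provenance-headed CSV
read_climate_agnostic <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
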