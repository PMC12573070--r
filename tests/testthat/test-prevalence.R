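make_toy_specimens <- function(n = 300, S = 2, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    species = sample(paste0("sp", 1:S), n, replace = TRUE),
    year = sample(1850:2019, n, replace = TRUE),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    collector_id = sample(paste0("c", 1:8), n, replace = TRUE),
    scorer_id = sample(paste0("s", 1:5), n, replace = TRUE),
    status_liberal = rbinom(n, 1, 0.5)
  ) |>
    dplyr::mutate(status_conservative = status_liberal)
}

test_that("latent dimension follows the model structure arithmetic", {
  d <- make_toy_specimens(400, S = 3, seed = 2)
  m <- test_mesh()
  model <- assemble_joint_model(d, m)
  S <- 3; mm <- m$n_vertices
  expect_equal(model$p, 2 * S + (2 * S + 1) * mm + 8 + 5)
  # a record's design row touches: 2 fixed, <=3 alpha, <=3 tau, <=3 delta,
  # 1 collector, 1 scorer
  row <- model$A[1, ]
  expect_lte(sum(row != 0), 2 + 3 + 3 + 3 + 1 + 1)
  idx <- model$idx
  expect_equal(sum(row[idx$fixed] != 0), 2)
  expect_equal(sum(row[idx$collector] != 0), 1)
  expect_equal(sum(row[idx$scorer] != 0), 1)
  expect_lte(sum(row[idx$delta] != 0), 3)
  # index map partitions the latent vector exactly
  expect_equal(sort(unlist(model$idx)), 1:model$p, ignore_attr = TRUE)
})

test_that("fixed-effects-only joint fit matches per-species IRLS oracles", {
  d <- make_toy_specimens(500, S = 2, seed = 3)
  spec <- prevalence_model_spec(components = character(0))
  model <- assemble_joint_model(d, test_mesh(), spec)
  fit <- fit_prevalence_model(model, optimize = FALSE)
  td <- tidy(fit)
  for (sp in c("sp1", "sp2")) {
    ds <- d[d$species == sp, ]
    yr <- (ds$year - 1920) / 100
    oracle <- irls_logistic(cbind(1, yr), ds$status_liberal, prec = 1e-3)
    est <- c(td$estimate[td$term == "intercept" & td$species == sp],
             td$estimate[td$term == "slope" & td$species == sp])
    expect_lt(max(abs(est - oracle)), 1e-6)
  }
})

test_that("unknown species and missing columns raise schema errors", {
  d <- make_toy_specimens(50)
  expect_error(assemble_joint_model(d[, -1], test_mesh()), "missing columns")
  spec <- prevalence_model_spec()
  expect_error(
    assemble_joint_model(dplyr::select(d, -collector_id), test_mesh(), spec),
    "collector_id")
  expect_error(prevalence_model_spec(components = "banana"), "unknown")
  expect_error(prevalence_model_spec(year_scale = 0), "year_scale")
})

test_that("an all-null truth yields a flat surface near one half", {
  cfg <- quick_config(n_specimens_per_species = 1500, intercept = 0,
                      slope = 0, sd_alpha = 0, sd_tau = 0, sd_delta = 0,
                      sd_collector = 0, sd_scorer = 0, rng_seed = 14)
  sim <- simulate_specimens(cfg, test_mesh())
  model <- assemble_joint_model(sim$specimens, test_mesh())
  fit <- fit_prevalence_model(model, optimize = FALSE,
                              theta = endotrend:::bias_true_theta(model, cfg))
  pg <- pixel_grid(c(0, 1000, 0, 1000), nx = 6, ny = 6)
  surf <- predict_prevalence(fit, pg, 1950, n_samples = 300)
  expect_true(all(abs(surf$mean - 0.5) < 0.15))
  expect_true(all(surf$mean > 0 & surf$mean < 1))
  expect_true(all(surf$q2.5 <= surf$q50 & surf$q50 <= surf$q97.5))
})

test_that("logit difference between years is the slope identity at the mode", {
  cfg <- quick_config(rng_seed = 5)
  sim <- simulate_specimens(cfg, test_mesh())
  model <- assemble_joint_model(sim$specimens, test_mesh())
  fit <- fit_prevalence_model(model, optimize = FALSE)
  pg <- pixel_grid(c(100, 900, 100, 900), nx = 4, ny = 4)
  sp <- fit$species[1]
  L0 <- endotrend:::prediction_linear_map(fit, pg, 1895, sp)
  L1 <- endotrend:::prediction_linear_map(fit, pg, 2020, sp)
  eta0 <- as.numeric(L0 %*% fit$fit$mode)
  eta1 <- as.numeric(L1 %*% fit$fit$mode)
  # (T_h + tau_h(l)) * dyr exactly, dyr = 1.25 scaled units
  Tg <- fit$fit$mode[endotrend:::fixed_index(fit, "T", sp)]
  P <- mesh_projector(test_mesh(), pg)
  tau_l <- as.numeric(P %*% fit$fit$mode[model$idx[[paste0("tau_", sp)]]])
  expect_equal(eta1 - eta0, (Tg + tau_l) * 1.25, tolerance = 1e-10)
})

test_that("annualized slopes are bounded and near zero under a null trend", {
  cfg <- quick_config(n_specimens_per_species = 3000, intercept = 0,
                      slope = 0, sd_alpha = 0.3, sd_tau = 0, sd_delta = 0.2,
                      rng_seed = 31)
  sim <- simulate_specimens(cfg, test_mesh())
  model <- assemble_joint_model(sim$specimens, test_mesh())
  fit <- fit_prevalence_model(model, optimize = FALSE,
                              theta = endotrend:::bias_true_theta(model, cfg))
  pg <- pixel_grid(c(0, 1000, 0, 1000), nx = 6, ny = 6)
  ss <- svc_slope_surface(fit, pg, n_samples = 300)
  expect_true(all(abs(ss$mean) <= 1 / 125))
  expect_gte(mean(abs(ss$mean) < 0.002), 0.95)
})

test_that("predictions are invariant to collector and scorer relabeling", {
  d <- make_toy_specimens(400, S = 1, seed = 8)
  m <- test_mesh()
  fit1 <- fit_prevalence_model(assemble_joint_model(d, m), optimize = FALSE)
  # bijective relabeling of collector ids
  d2 <- d
  d2$collector_id <- paste0("z", match(d$collector_id,
                                       sort(unique(d$collector_id))))
  d2$scorer_id <- paste0("q", 6 - match(d$scorer_id,
                                        sort(unique(d$scorer_id))))
  fit2 <- fit_prevalence_model(assemble_joint_model(d2, m), optimize = FALSE)
  pg <- pixel_grid(c(200, 800, 200, 800), nx = 3, ny = 3)
  # compare the exact posterior-mode predictions (sampling noise excluded)
  L1 <- endotrend:::prediction_linear_map(fit1, pg, 1950, "sp1")
  L2 <- endotrend:::prediction_linear_map(fit2, pg, 1950, "sp1")
  eta1 <- as.numeric(L1 %*% fit1$fit$mode)
  eta2 <- as.numeric(L2 %*% fit2$fit$mode)
  expect_equal(eta1, eta2, tolerance = 1e-6)
})

test_that("global slope sign probability behaves like a posterior tail", {
  cfg <- quick_config(n_specimens_per_species = 2000, slope = 2,
                      sd_tau = 0.3, rng_seed = 41)
  sim <- simulate_specimens(cfg, test_mesh())
  model <- assemble_joint_model(sim$specimens, test_mesh())
  fit <- fit_prevalence_model(model, optimize = FALSE,
                              theta = endotrend:::bias_true_theta(model, cfg))
  pp <- probability_positive_global_slope(fit, n_samples = 2000)
  expect_gte(pp$prob_positive, 0.99) # strong simulated trend
  # complement identity on the same samples
  s <- endotrend:::sample_latent(fit$fit, 2000, seed = 1)
  j <- endotrend:::fixed_index(fit, "T", fit$species[1])
  expect_equal(mean(s[j, ] > 0) + mean(s[j, ] <= 0), 1)
})

test_that("binned prevalence computes exact proportions", {
  d <- tibble::tibble(
    species = "sp", year = c(1901, 1904, 1909, 1911, 1918, 1919),
    status_liberal = c(1, 0, 1, 1, 0, 0))
  b <- binned_observed_prevalence(d, bin_width = 10)
  expect_equal(b$bin_mid, c(1905, 1915))
  expect_equal(b$n, c(3, 3))
  expect_equal(b$prevalence, c(2 / 3, 1 / 3))
  expect_equal(sum(b$n), nrow(d))
  # all-positive records give prevalence one in every bin
  d$status_liberal <- 1
  expect_true(all(binned_observed_prevalence(d, 10)$prevalence == 1))
  expect_error(binned_observed_prevalence(d, 0), "bin_width")
})
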