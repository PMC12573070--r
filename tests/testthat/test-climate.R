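toy_climate <- function() {
  # 2 pixels x 2 years x 12 months, hand-checkable values
  g <- tidyr::expand_grid(pixel_id = 1:2, year = 2000:2001, month = 1:12)
  g$x <- g$pixel_id * 10
  g$y <- 0
  temp <- dplyr::mutate(g, variable = "temperature",
                        value = 10 + pixel_id + (month %% 4))
  prec <- dplyr::mutate(g, variable = "precipitation",
                        value = 10 * month)
  dplyr::bind_rows(temp, prec)
}

test_that("seasonal values are means for temperature and sums for precipitation", {
  sv <- seasonal_values(toy_climate())
  # spring temperature, pixel 1: months 1..4 -> values 11 + c(1,2,3,0)
  v <- sv$value[sv$pixel_id == 1 & sv$season == "spring" &
                  sv$variable == "temperature" & sv$year == 2000]
  expect_equal(v, mean(11 + c(1, 2, 3, 0)))
  # spring precipitation: 10+20+30+40 = 100
  p <- sv$value[sv$pixel_id == 1 & sv$season == "spring" &
                  sv$variable == "precipitation" & sv$year == 2000]
  expect_equal(p, 100)
  # autumn precipitation: 90+100+110+120
  pa <- sv$value[sv$pixel_id == 2 & sv$season == "autumn" &
                   sv$variable == "precipitation" & sv$year == 2001]
  expect_equal(pa, sum(10 * (9:12)))
  # constant temperature gives its own value back
  cl <- dplyr::mutate(toy_climate(), value = 10)
  expect_true(all(seasonal_values(cl)$value[
    seasonal_values(cl)$variable == "temperature"] == 10 |
      seasonal_values(cl)$variable != "temperature"))
})

test_that("missing months exclude the pixel-year season with a warning", {
  cl <- toy_climate()
  cl <- cl[!(cl$pixel_id == 1 & cl$year == 2000 & cl$month == 2 &
               cl$variable == "temperature"), ]
  expect_warning(sv <- seasonal_values(cl), "missing months")
  expect_false(any(sv$pixel_id == 1 & sv$year == 2000 &
                     sv$season == "spring" & sv$variable == "temperature"))
})

test_that("climate normals have closed-form means and sds", {
  # constant series: sd exactly 0
  yrs <- 1990:2020
  sv <- tibble::tibble(pixel_id = 1, x = 0, y = 0, year = yrs,
                       season = "spring", variable = "temperature",
                       value = 7)
  nn <- climate_normals(sv, c(1990, 2020))
  expect_equal(nn$mean, 7)
  expect_equal(nn$sd, 0)
  expect_equal(nn$n_years, 31L)
  # linear series a + b t over 31 years: sd = b sqrt(sum((t - tbar)^2) / 30)
  b <- 0.13
  sv2 <- dplyr::mutate(sv, value = 2 + b * (year - 1990))
  nn2 <- climate_normals(sv2, c(1990, 2020))
  t <- 0:30
  expect_equal(nn2$sd, b * sqrt(sum((t - mean(t))^2) / 30), tolerance = 1e-12)
  # below completeness threshold: masked with warning
  sv3 <- sv[1:10, ]
  expect_warning(n3 <- climate_normals(sv3, c(1990, 2020)), "masked")
  expect_equal(nrow(n3), 0)
  # identical periods give zero delta
  svb <- dplyr::bind_rows(sv2, dplyr::mutate(sv2, year = year - 95))
  dd <- climate_deltas(svb, historic = c(1895, 1925), recent = c(1990, 2020))
  expect_equal(max(abs(dd$delta)), 0, tolerance = 1e-12)
})

test_that("pixel subsampling is uniform, reproducible, and bounded", {
  pix <- pixel_grid(c(0, 100, 0, 100), nx = 10, ny = 10)
  expect_error(subsample_pixels(pix, 101), "exceeds")
  all_of_them <- subsample_pixels(pix, 100, seed = 2)
  expect_setequal(all_of_them$pixel_id, pix$pixel_id)
  s1 <- subsample_pixels(pix, 25, seed = 7)
  s2 <- subsample_pixels(pix, 25, seed = 7)
  expect_identical(s1, s2)
  # inclusion frequency ~ n/N over reseeded draws
  hits <- 0
  for (r in 1:400) hits <- hits +
    (1 %in% subsample_pixels(pix, 25, seed = r)$pixel_id)
  p <- 25 / 100
  expect_lt(abs(hits / 400 - p), 3 * sqrt(p * (1 - p) / 400))
})

test_that("post-hoc regression recovers exact and least-squares slopes", {
  dv <- seq(-1, 1, length.out = 40)
  deltas <- tibble::tibble(pixel_id = 1:40, x = 0, y = 0,
                           driver = "spring_temperature_mean",
                           season = "spring", variable = "temperature",
                           stat = "mean", delta = dv)
  # noiseless y = 2x (trend in % per year = 2 * delta)
  slopes <- tibble::tibble(pixel_id = 1:40, mean = 2 * dv / 100)
  r <- suppressWarnings(posthoc_regression(slopes, deltas)) # lm: perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_gt(r$prob_positive, 1 - 1e-10)
  expect_equal(r$prob_positive + r$prob_negative, 1)
  expect_equal(r$unit, "per degree C")

  # 5-point hand dataset against the normal equations
  xv <- c(0.1, 0.5, -0.3, 0.9, -0.7)
  yv <- c(0.2, 1.1, -0.4, 1.3, -0.9)
  d5 <- tibble::tibble(pixel_id = 1:5, x = 0, y = 0,
                       driver = "summer_precipitation_mean",
                       season = "summer", variable = "precipitation",
                       stat = "mean", delta = xv * 100) # per-100mm scaling
  s5 <- tibble::tibble(pixel_id = 1:5, mean = yv / 100)
  r5 <- posthoc_regression(s5, d5)
  bhat <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
  expect_equal(r5$slope, bhat, tolerance = 1e-10)
  expect_equal(r5$unit, "per 100 mm")

  # constant covariate: singular design error naming the driver
  dc <- dplyr::mutate(deltas, delta = 1)
  expect_error(posthoc_regression(slopes, dc), "spring_temperature_mean")
})

test_that("null couplings give calibrated sign probabilities", {
  set.seed(60)
  inside <- 0
  n_rep <- 200
  for (r in 1:n_rep) {
    dv <- rnorm(250)
    yv <- rnorm(250)
    deltas <- tibble::tibble(pixel_id = 1:250, x = 0, y = 0,
                             driver = "d", season = "spring",
                             variable = "temperature", stat = "mean",
                             delta = dv)
    slopes <- tibble::tibble(pixel_id = 1:250, mean = yv / 100)
    pr <- posthoc_regression(slopes, deltas)$prob_positive
    inside <- inside + (pr >= 0.025 && pr <= 0.975)
  }
  expect_gte(inside / n_rep, 0.93)
})

test_that("joint-mode regression agrees with lm on multiple drivers", {
  set.seed(61)
  n <- 120
  d1 <- rnorm(n); d2 <- rnorm(n)
  y <- 1.5 * d1 - 0.5 * d2 + rnorm(n, 0, 0.3)
  deltas <- dplyr::bind_rows(
    tibble::tibble(pixel_id = 1:n, x = 0, y = 0, driver = "a",
                   season = "spring", variable = "temperature",
                   stat = "mean", delta = d1),
    tibble::tibble(pixel_id = 1:n, x = 0, y = 0, driver = "b",
                   season = "summer", variable = "temperature",
                   stat = "mean", delta = d2))
  slopes <- tibble::tibble(pixel_id = 1:n, mean = y / 100)
  r <- posthoc_regression(slopes, deltas, mode = "joint")
  oracle <- coef(lm(y ~ d1 + d2))
  expect_equal(sort(r$slope), sort(unname(oracle[2:3])), tolerance = 1e-8)
})
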