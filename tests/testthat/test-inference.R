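test_that("joint negative log posterior matches closed forms", {
  n <- 20
  m0 <- latent_model(rep(0:1, n / 2), list(fixed = block_fixed(matrix(1, n, 1),
                                                               prec = 1)))
  # zero latent vector: likelihood term is n ln 2; prior adds its constants
  val <- joint_neg_log_posterior(m0, 0)
  const <- 0.5 * log(2 * pi) - 0.5 * log(1) # p = 1, Q = 1
  expect_equal(val, n * log(2) + const, tolerance = 1e-10)
  # single observation y=1 with eta=3: likelihood term ln(1 + e^-3)
  m1 <- latent_model(1, list(fixed = block_fixed(matrix(1, 1, 1), prec = 1)))
  lik <- joint_neg_log_posterior(m1, 3) - (0.5 * 9 + 0.5 * log(2 * pi))
  expect_equal(lik, log(1 + exp(-3)), tolerance = 1e-10)
  expect_equal(log(1 + exp(-3)), 0.048587, tolerance = 1e-5)
  # standard-normal prior, unit latent vector of length k: quadratic form k/2
  k <- 7
  mk <- latent_model(rep(1, k),
                     list(fixed = block_fixed(diag(k), prec = 1)))
  quad <- joint_neg_log_posterior(mk, rep(1, k)) -
    (k * log1p(exp(1)) - sum(rep(1, k))) - 0.5 * k * log(2 * pi)
  expect_equal(quad, k / 2, tolerance = 1e-10)
  expect_error(joint_neg_log_posterior(mk, rep(1, k + 1)), "length")
})

test_that("Laplace mode equals the IRLS oracle for penalized logistic fits", {
  set.seed(17)
  for (i in 1:5) {
    n <- 60 + 20 * i
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- rbinom(n, 1, plogis(X %*% c(-0.3, 0.8, -0.5)))
    model <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3)))
    mode <- find_mode(model)
    oracle <- irls_logistic(X, y, prec = 1e-3)
    expect_lt(max(abs(mode$mode - oracle)), 1e-6)
    expect_true(mode$converged)
  }
})

test_that("Gaussian (identity-link) models converge immediately and exactly", {
  set.seed(2)
  X <- cbind(1, rnorm(30))
  y <- as.numeric(X %*% c(1, 2)) + rnorm(30, 0, 0.5)
  model <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-8)),
                        family = "gaussian", gaussian_sd = 0.5)
  mode <- find_mode(model)
  expect_lte(mode$iter, 2) # quadratic objective: one Newton step
  expect_true(mode$converged)
})

test_that("separable data keep a finite mode under the vague prior", {
  y <- c(rep(0, 10), rep(1, 10))
  X <- cbind(1, c(seq(-1, -0.1, length.out = 10),
                  seq(0.1, 1, length.out = 10)))
  model <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3)))
  mode <- find_mode(model, max_iter = 200)
  expect_true(all(is.finite(mode$mode)))
  expect_lt(max(abs(mode$mode)), 1e3) # bounded by the prior
})

test_that("log marginal likelihood is exact for the conjugate Gaussian toy", {
  q <- 2.5; s <- 0.7
  for (yv in c(-1.2, 0.4, 3)) {
    model <- latent_model(yv, list(fixed = block_fixed(matrix(1, 1, 1),
                                                       prec = q)),
                          family = "gaussian", gaussian_sd = s)
    lml <- log_marginal_likelihood(model)
    expect_equal(lml, dnorm(yv, 0, sqrt(1 / q + s^2), log = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("marginal likelihood is invariant to observation and block order", {
  set.seed(5)
  n <- 120
  X <- cbind(1, rnorm(n))
  grp <- sample(1:6, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(X %*% c(0.2, 0.9)))
  m1 <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3),
                             g = block_iid(grp, sd = 0.5, estimate = FALSE)))
  perm <- sample.int(n)
  m2 <- latent_model(y[perm],
                     list(fixed = block_fixed(X[perm, ], prec = 1e-3),
                          g = block_iid(grp[perm], sd = 0.5,
                                        estimate = FALSE)))
  m3 <- latent_model(y, list(g = block_iid(grp, sd = 0.5, estimate = FALSE),
                             fixed = block_fixed(X, prec = 1e-3)))
  l1 <- log_marginal_likelihood(m1)
  expect_equal(log_marginal_likelihood(m2), l1, tolerance = 1e-9)
  expect_equal(log_marginal_likelihood(m3), l1, tolerance = 1e-9)
})

test_that("destroying structure lowers the marginal likelihood", {
  set.seed(31)
  mesh <- test_mesh()
  fem <- test_fem()
  wins <- 0
  for (r in 1:8) {
    w <- sample_gp_field(mesh, 300, 1.5, seed = 100 + r, fem = fem)
    n <- 400
    loc <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
    A <- mesh_projector(mesh, loc)
    y <- rbinom(n, 1, plogis(as.numeric(A %*% w)))
    if (length(unique(y)) < 2) next
    mk <- function(yy) latent_model(
      yy, list(field = block_field(A, fem, range = 300, sigma = 1.5,
                                   estimate = FALSE)))
    l_obs <- log_marginal_likelihood(mk(y))
    l_perm <- log_marginal_likelihood(mk(sample(y)))
    wins <- wins + (l_perm < l_obs)
  }
  expect_gte(wins, 7) # permutation destroys the spatial signal
})

test_that("an irrelevant near-zero field leaves the evidence unchanged", {
  set.seed(9)
  n <- 100
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, plogis(X %*% c(0, 1)))
  A0 <- Matrix::sparseMatrix(i = 1:n, j = sample(1:10, n, TRUE), x = 1,
                             dims = c(n, 10))
  base <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3)))
  plus <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3),
                               tiny = block_iid(sample(1:10, n, TRUE),
                                                sd = 1e-5,
                                                estimate = FALSE)))
  expect_equal(log_marginal_likelihood(plus), log_marginal_likelihood(base),
               tolerance = 1e-4)
})

test_that("flat likelihood pushes hyperparameters to the PC prior mode", {
  # a field whose projector is identically zero: data carry no information
  n <- 30
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(n, test_mesh()$n_vertices))
  model <- latent_model(rep(0:1, 15),
                        list(fixed = block_fixed(matrix(1, n, 1),
                                                 prec = 1e-3),
                             f = block_field(A0, test_fem(), range = 200,
                                             sigma = 0.5,
                                             prior = pc_prior_field())))
  fit <- optimize_hyperparameters(model, maxit = 300, restart = FALSE)
  pr <- pc_prior_field()
  # log-scale prior modes: rho = lambda_rho, sigma = 1 / lambda_sigma
  expect_equal(exp(fit$theta[[1]]), pr$lambda_rho, tolerance = 0.05)
  expect_equal(exp(fit$theta[[2]]), 1 / pr$lambda_sigma, tolerance = 0.05)
})

test_that("hyperparameter optimization recovers range and iid sd", {
  mesh <- test_mesh()
  fem <- test_fem()
  ok <- 0
  for (r in 1:5) {
    set.seed(700 + r)
    w <- sample_gp_field(mesh, 300, 1, fem = fem)
    n <- 1200
    loc <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
    A <- mesh_projector(mesh, loc)
    y <- rbinom(n, 1, plogis(as.numeric(A %*% w)))
    model <- latent_model(y, list(f = block_field(A, fem, range = 342,
                                                  sigma = 1)))
    fit <- optimize_hyperparameters(model, maxit = 80, restart = FALSE)
    rho_hat <- exp(fit$theta[[1]])
    ok <- ok + (rho_hat >= 150 && rho_hat <= 600)
  }
  expect_gte(ok, 4) # range recovery within a factor ~2 most of the time

  # iid-only model: collector sd within +-50% at 50 x 40 records
  set.seed(55)
  grp <- rep(1:50, each = 40)
  eff <- rnorm(50, 0, 1)
  y <- rbinom(length(grp), 1, plogis(eff[grp]))
  model <- latent_model(y, list(g = block_iid(grp, sd = 0.5)))
  fit <- optimize_hyperparameters(model, maxit = 60, restart = FALSE)
  expect_gt(exp(fit$theta[[1]]), 0.5)
  expect_lt(exp(fit$theta[[1]]), 1.5)
})

test_that("posterior samples agree with the dense-covariance oracle", {
  set.seed(77)
  n <- 150
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(X %*% c(0, 1, -1)))
  model <- latent_model(y, list(fixed = block_fixed(X, prec = 1e-3)))
  fit <- lgm_fit(model)
  expect_error(sample_latent(fit, 1), "n_samples")
  s <- sample_latent(fit, 4000, seed = 12)
  # mean matches the mode within Monte Carlo error (3 sd / sqrt(n))
  sds <- sqrt(diag(solve(as.matrix(fit$precision))))
  expect_true(all(abs(rowMeans(s) - fit$mode) < 3 * sds / sqrt(4000) * 1.5))
  # variance of a fixed linear functional vs the dense inverse
  v <- c(1, -2, 0.5)
  oracle_var <- as.numeric(v %*% solve(as.matrix(fit$precision)) %*% v)
  expect_equal(var(as.numeric(v %*% s)), oracle_var, tolerance = 0.1)
  # transformed summaries live in (0, 1) with ordered quantiles
  sm <- summarize_functionals(fit, rbind(v, -v), transform = plogis,
                              n_samples = 500, seed = 3)
  expect_true(all(sm$q2.5 <= sm$q25 & sm$q25 <= sm$q50 &
                    sm$q50 <= sm$q75 & sm$q75 <= sm$q97.5))
  expect_true(all(sm$mean > 0 & sm$mean < 1))
})
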