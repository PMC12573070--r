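# shared small fixtures, built in code at test time

# coarse mesh over a 1000 km square, ~220 nodes
test_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pts <- expand.grid(x = seq(0, 1000, length.out = 8),
                         y = seq(0, 1000, length.out = 8))
      cache <<- suppressMessages(
        build_mesh(pts, cutoff = 5, max_edge = 150, extension = 200))
    }
    cache
  }
})

test_fem <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fem_matrices(test_mesh())
    cache
  }
})

# independent ridge-penalized IRLS oracle for logistic regression
irls_logistic <- function(X, y, prec = 1e-3, iter = 200) {
  b <- numeric(ncol(X))
  for (i in seq_len(iter)) {
    eta <- as.numeric(X %*% b)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    H <- t(X) %*% (W * X) + prec * diag(ncol(X))
    g <- t(X) %*% (y - mu) - prec * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  as.numeric(b)
}

# brute-force AUC over all positive-negative pairs, ties counted 1/2
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small, fast simulation configuration used in several suites
quick_config <- function(...) {
  defaults <- list(
    domain_extent = c(0, 1000, 0, 1000),
    n_species = 1, n_specimens_per_species = 800,
    year_range = c(1895, 2020),
    intercept = 0, slope = 1.5,
    field_range = 342, sd_alpha = 0.8, sd_tau = 0.8, sd_delta = 0.3,
    n_collectors = 20, n_scorers = 10,
    sd_collector = 0.2, sd_scorer = 0.3
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
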