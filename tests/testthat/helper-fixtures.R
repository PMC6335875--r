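# small cohorts and random regression problems shared across test files

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 4, n_features = 100, n_trend = 10,
         n_circadian = 10, n_condition = 10, n_mixed = 5,
         flag_rate = 0.05, seed = 7L),
    list(...))
  do.call(synthetic_config, args)
}

# random dense regression problem with named features
random_problem <- function(n, p, k = 3, snr_beta = 1.5, noise = 0.5,
                           seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  beta <- c(rep(snr_beta, k), rep(0, p - k))
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}

# elastic-net objective on the standardized scale (independent of the
# solver internals), for optimality checks
enet_objective <- function(X, y, b0, beta_orig, lambda, alpha) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  bs <- beta_orig * s
  r <- y - b0 - drop(X %*% beta_orig)
  sum(r^2) / (2 * length(y)) +
    lambda * (alpha * sum(abs(bs)) + (1 - alpha) / 2 * sum(bs^2))
}

# KKT / subgradient residuals of a fit under the package objective,
# computed from scratch on the standardized design
kkt_residuals <- function(X, y, model) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  bs <- model$beta * s
  r <- y - model$intercept - drop(X %*% model$beta)
  n <- length(y)
  g <- drop(crossprod(Xs, r)) / n
  la <- model$lambda * model$alpha
  l2 <- model$lambda * (1 - model$alpha)
  active <- bs != 0
  viol_zero <- if (any(!active)) max(abs(g[!active]) - la, 0) else 0
  viol_act <- if (any(active))
    max(abs(g[active] - l2 * bs[active] - la * sign(bs[active]))) else 0
  max(viol_zero, viol_act)
}
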