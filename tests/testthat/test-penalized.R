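test_that("soft thresholding operator", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  z <- c(-2, -0.1, 0, 0.1, 2)
  expect_equal(soft_threshold(z, 0), z)      # identity at zero threshold
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("full shrinkage yields the null model", {
  pr <- random_problem(40, 10, seed = 3)
  m <- fit_penalized(pr$X, pr$y, "linear", alpha = 0.5, lambda = 1e6)
  expect_equal(unname(m$beta), rep(0, 10))
  expect_equal(m$intercept, mean(pr$y))
  yb <- rep(c(0, 1), c(15, 25))
  ml <- fit_penalized(pr$X, yb, "logistic", alpha = 0.5, lambda = 1e6)
  expect_equal(unname(ml$beta), rep(0, 10))
  expect_equal(ml$intercept, log(25 / 15), tolerance = 1e-5)
  expect_length(nonzero_panel(m), 0)
})

test_that("orthonormal single-feature fit matches the soft-threshold closed form", {
  set.seed(4)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  X <- matrix(x, n, 1, dimnames = list(NULL, "f1"))
  y <- 0.8 * x + rnorm(n, 0, 0.3)
  b <- mean(x * y)  # OLS coefficient on the standardized feature
  for (lambda in c(0.05, 0.3)) for (alpha in c(0.5, 1)) {
    m <- fit_penalized(X, y, "linear", alpha = alpha, lambda = lambda)
    expect_equal(unname(m$beta),
                 soft_threshold(b, lambda * alpha) /
                   (1 + lambda * (1 - alpha)),
                 tolerance = 1e-6)
  }
  # a coefficient below lambda*alpha is excluded from the panel
  m0 <- fit_penalized(X, y, "linear", alpha = 1, lambda = abs(b) * 1.01)
  expect_length(nonzero_panel(m0), 0)
})

test_that("ridge fits match the closed form", {
  pr <- random_problem(60, 8, seed = 5)
  n <- nrow(pr$X)
  mu <- colMeans(pr$X)
  s <- sqrt(colMeans(sweep(pr$X, 2, mu)^2))
  Xs <- sweep(sweep(pr$X, 2, mu), 2, s, "/")
  for (lambda in c(0.1, 1)) {
    closed <- solve(crossprod(Xs) / n + lambda * diag(8),
                    crossprod(Xs, pr$y - mean(pr$y)) / n)
    m <- fit_penalized(pr$X, pr$y, "linear", alpha = 0, lambda = lambda)
    expect_equal(unname(m$beta), drop(closed) / s, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # ridge keeps every feature in the panel
    expect_length(nonzero_panel(m), 8)
  }
})

test_that("subgradient optimality holds on random 20-feature problems", {
  worst <- 0
  for (i in 1:50) {
    pr <- random_problem(40, 20, k = 4, seed = 100 + i)
    alpha <- sample(c(0.2, 0.5, 0.8, 1), 1)
    lambda <- stats::runif(1, 0.02, 0.5)
    m <- fit_penalized(pr$X, pr$y, "linear", alpha = alpha,
                       lambda = lambda)
    worst <- max(worst, kkt_residuals(pr$X, pr$y, m))
  }
  expect_lt(worst, 1e-5)
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  pr <- random_problem(50, 30, seed = 8)
  m <- fit_penalized(pr$X, pr$y, "linear", alpha = 0.5, lambda = 0.05)
  expect_true(all(diff(m$objective) <= 1e-12))
  yb <- as.integer(pr$y > median(pr$y))
  ml <- fit_penalized(pr$X, yb, "logistic", alpha = 0.5, lambda = 0.02)
  expect_gt(length(ml$objective), 1)
})

test_that("warm-started path solutions match cold-started fits", {
  pr <- random_problem(60, 40, k = 5, seed = 9)
  grid <- lambda_grid(pr$X, pr$y, "linear", 0.5, n_lambda = 30)
  path <- fit_penalized_path(pr$X, pr$y, "linear", 0.5, grid, tol = 1e-9)
  for (l in c(5, 15, 30)) {
    cold <- fit_penalized(pr$X, pr$y, "linear", 0.5, lambda = grid[l],
                          tol = 1e-9)
    expect_equal(unname(path$beta[, l]), unname(cold$beta),
                 tolerance = 1e-6)
  }
})

test_that("lambda grid: null fit at the top, shape, and ratio behavior", {
  pr <- random_problem(50, 25, seed = 10)
  g <- lambda_grid(pr$X, pr$y, "linear", 0.5, n_lambda = 40)
  expect_length(g, 40)
  expect_true(all(diff(g) < 0))
  m_top <- fit_penalized(pr$X, pr$y, "linear", 0.5, lambda = g[1])
  expect_length(nonzero_panel(m_top), 0)
  # and the grid point just below the top activates something
  m_next <- fit_penalized(pr$X, pr$y, "linear", 0.5,
                          lambda = g[1] * 0.98)
  expect_gte(length(nonzero_panel(m_next)), 1)
  g2 <- lambda_grid(pr$X, pr$y, "linear", 0.5, n_lambda = 40,
                    lambda_min_ratio = 5e-4)
  expect_equal(g2[1], g[1])
  expect_lt(g2[40], g[40])
})

test_that("agreement with glmnet on random problems", {
  skip_if_not_installed("glmnet")
  suppressMessages(library(glmnet))
  for (i in 1:5) {
    pr <- random_problem(80, 20, k = 4, seed = 200 + i)
    # unit-variance response aligns the gaussian penalty conventions
    y <- pr$y / sqrt(mean((pr$y - mean(pr$y))^2))
    lam <- c(0.3, 0.1, 0.05)[1 + i %% 3]
    m <- fit_penalized(pr$X, y, "linear", alpha = 0.5, lambda = lam)
    g <- glmnet(pr$X, y, alpha = 0.5, lambda = lam, thresh = 1e-12)
    expect_lt(max(abs(c(m$intercept, m$beta) - as.numeric(coef(g)))),
              1e-4)
    yb <- as.integer(drop(pr$X %*% pr$beta) + rnorm(80) > 0)
    ml <- fit_penalized(pr$X, yb, "logistic", alpha = 0.5, lambda = 0.05)
    gl <- glmnet(pr$X, yb, family = "binomial", alpha = 0.5,
                 lambda = 0.05, thresh = 1e-12)
    expect_lt(max(abs(c(ml$intercept, ml$beta) - as.numeric(coef(gl)))),
              1e-4)
  }
})

test_that("prediction semantics: alignment, link, monotonicity", {
  pr <- random_problem(30, 6, seed = 12)
  m <- fit_penalized(pr$X, pr$y, "linear", alpha = 0.5, lambda = 0.05)
  # feature alignment by name, any column order
  perm <- pr$X[, sample(ncol(pr$X))]
  expect_equal(predict(m, perm), predict(m, pr$X))
  expect_error(predict(m, pr$X[, 1:3]), "missing")
  # all-zero logistic model scores 0.5 everywhere
  null_model <- structure(list(intercept = 0,
                               beta = setNames(rep(0, 6), colnames(pr$X)),
                               family = "logistic", alpha = 0.5,
                               lambda = 1), class = "penalized_model")
  expect_equal(unname(predict(null_model, pr$X)), rep(0.5, 30))
  # constant linear model
  const <- structure(list(intercept = 24,
                          beta = setNames(rep(0, 6), colnames(pr$X)),
                          family = "linear", alpha = 0.5, lambda = 1),
                     class = "penalized_model")
  expect_equal(unname(predict(const, pr$X)), rep(24, 30))
  # monotone in a positively weighted feature
  j <- which(m$beta > 0)[1]
  skip_if(is.na(j))
  X2 <- pr$X; X2[, j] <- X2[, j] + 1
  expect_true(all(predict(m, X2) >= predict(m, pr$X)))
})

test_that("model serialization round-trips through TSV", {
  pr <- random_problem(30, 6, seed = 13)
  m <- fit_penalized(pr$X, pr$y, "linear", alpha = 0.5, lambda = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$beta, m$beta)
  expect_equal(back$intercept, m$intercept)
  expect_equal(predict(back, pr$X), predict(m, pr$X))
})
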