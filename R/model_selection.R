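#' Repeated stratified k-fold cross-validation for lambda
#'
#' The panel-selection tuning rule: folds are assigned at random -- with
#' respect to class balance for classification targets (and, optionally, a
#' user-supplied stratum for regression targets) -- the held-out error is
#' averaged per lambda over a shared grid, the per-repeat optimum is the
#' argmin (ties resolved to the larger lambda, i.e. the sparser model), and
#' the final lambda is the arithmetic mean of the per-repeat optima.
#' Held-out error is mean squared error for the linear family and mean
#' binomial deviance for the logistic family.
#'
#' @inheritParams fit_penalized
#' @param k number of folds; reduced with a warning when a class is too
#'   small to stratify at \code{k}.
#' @param repeats number of random fold assignments (500 in the full-scale
#'   analysis; smaller values are appropriate desk-scale defaults).
#' @param seed RNG seed for fold assignment.
#' @param n_lambda,lambda_min_ratio grid shape (see
#'   \code{\link{lambda_grid}}).
#' @param strata optional factor for stratified fold assignment with a
#'   linear target (e.g. the condition label); ignored for logistic, which
#'   stratifies on the class.
#' @return object of class \code{cv_result}: \code{lambda} (mean of the
#'   per-repeat selected lambdas), \code{lambda_per_repeat}, \code{grid},
#'   \code{cv_curve} (mean held-out error per grid lambda across repeats),
#'   \code{k}, \code{repeats}, \code{seed}.
#' @export
repeated_cv_lambda <- function(x, y, family = c("linear", "logistic"),
                               alpha = 0.5, k = 10, repeats = 500,
                               seed = 1L, n_lambda = 100,
                               lambda_min_ratio = 1e-3, strata = NULL,
                               tol = 1e-5) {
  family <- match.arg(family)
  chk <- check_xy(x, y, family)
  x <- chk$x; y <- chk$y
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 samples for cross-validation")
  if (n < k) {
    warning(sprintf("only %d samples; k reduced to %d", n, n))
    k <- n
  }
  st <- if (family == "logistic") factor(y)
        else if (!is.null(strata)) factor(strata)
        else factor(rep("all", n))
  min_str <- min(table(st))
  if (family == "logistic" && min_str < k) {
    warning(sprintf("class too small for %d folds; k reduced to %d",
                    k, min_str))
    k <- min_str
  }
  if (k < 2L) stop("stratified CV needs each class in >= 2 folds")
  grid <- lambda_grid(x, y, family, alpha, n_lambda, lambda_min_ratio)
  err_sum <- numeric(length(grid))
  sel <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- integer(n)
      for (lev in levels(st)) {
        idx <- which(st == lev)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      err <- matrix(NA_real_, n, length(grid))
      for (f in seq_len(k)) {
        ho <- folds == f
        fit <- fit_penalized_path(x[!ho, , drop = FALSE], y[!ho], family,
                                  alpha, grid, tol = tol)
        pred <- cbind(1, x[ho, , drop = FALSE]) %*%
          rbind(fit$intercept, fit$beta)
        err[ho, ] <- heldout_error(y[ho], pred, family)
      }
      curve <- colMeans(err)
      sel[r] <- grid[which.min(curve)]   # grid decreasing: ties -> larger
      err_sum <- err_sum + curve
    }
  })
  structure(list(lambda = mean(sel), lambda_per_repeat = sel, grid = grid,
                 cv_curve = err_sum / repeats, k = k, repeats = repeats,
                 seed = seed, family = family, alpha = alpha),
            class = "cv_result")
}

heldout_error <- function(y, pred, family) {
  if (family == "linear") return((y - pred)^2)
  p <- pmin(pmax(plogis(pred), 1e-10), 1 - 1e-10)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "repeated %d-fold CV (%d repeats): mean lambda = %.5g (sd %.3g)\n",
    x$k, x$repeats, x$lambda, stats::sd(x$lambda_per_repeat)))
  invisible(x)
}

#' Finalize a model at the cross-validated lambda
#'
#' One fit on the full training set at exactly the mean selected lambda of
#' the repeated-CV search (the lambda is honored as-is, never re-selected);
#' the biomarker panel is the nonzero-coefficient feature set.
#'
#' @inheritParams fit_penalized
#' @param cv a \code{cv_result} computed on the same training data.
#' @return a \code{penalized_model} with a \code{panel} attribute.
#' @export
finalize_model <- function(x, y, family = c("linear", "logistic"),
                           alpha = 0.5, cv, tol = 1e-7) {
  family <- match.arg(family)
  stopifnot(inherits(cv, "cv_result"))
  m <- fit_penalized(x, y, family, alpha, lambda = cv$lambda, tol = tol)
  attr(m, "panel") <- nonzero_panel(m)
  m
}

#' Write a CV result dump (repeat, selected_lambda) as TSV
#' @param cv a \code{cv_result}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  write_tsv(data.frame(repeat_id = seq_along(cv$lambda_per_repeat),
                       selected_lambda = cv$lambda_per_repeat), path)
}
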