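#' Leave-one-subject-out cross-validation of a labeled training set
#'
#' One fold per subject: all of that subject's units are removed, the
#' training-side computations are rerun from scratch on the remainder --
#' optional flag-based feature filtering, lambda tuning by repeated
#' stratified k-fold CV (at reduced repeats), and the final fit -- and the
#' held-out units are predicted by a model that never saw them. Pooled
#' held-out predictions yield the performance estimate. This respects the
#' trait-like within-subject correlation of the blood transcriptome that
#' ordinary sample-wise CV would leak.
#'
#' @param labeled a \code{labeled_set} (see \code{\link{assemble_variable}})
#'   or a list with \code{x}, \code{target}, \code{subjects}, \code{family}
#'   and optionally \code{flags}.
#' @param alpha elastic-net mixing weight.
#' @param k folds for the inner lambda search.
#' @param loso_repeats repeats for the inner lambda search (default 20; the
#'   full-scale rule uses 500, which is rarely worth the cost inside LOSO).
#' @param seed RNG seed; each fold derives its own child seed.
#' @param refit_lambda when FALSE, \code{lambda} is reused in every fold
#'   instead of being re-tuned.
#' @param lambda fixed lambda for \code{refit_lambda = FALSE}.
#' @param filter_flags rerun the flagged-feature filter within each fold
#'   (requires \code{labeled$flags}).
#' @param flag_threshold flagged-fraction cutoff for the per-fold filter.
#' @param n_lambda,lambda_min_ratio inner grid shape.
#' @param boundary decision boundary for classification metrics.
#' @return list of class \code{loso_result}: \code{predictions} (data.frame
#'   unit_id, subject, truth, score, predicted_class), \code{metrics}
#'   (\code{classification_metrics} or \code{regression_fit}),
#'   \code{lambda_per_fold}, \code{n_folds}, \code{skipped}.
#' @export
loso_cv <- function(labeled, alpha = 0.5, k = 10, loso_repeats = 20,
                    seed = 1L, refit_lambda = TRUE, lambda = NULL,
                    filter_flags = FALSE, flag_threshold = 0.10,
                    n_lambda = 100, lambda_min_ratio = 1e-3,
                    boundary = 0.5) {
  x <- labeled$x; y <- labeled$target; subjects <- labeled$subjects
  family <- labeled$family
  usub <- unique(subjects)
  if (length(usub) < 3L) stop("LOSO-CV needs >= 3 subjects")
  if (!refit_lambda && is.null(lambda))
    stop("`lambda` is required when refit_lambda = FALSE")
  scores <- rep(NA_real_, nrow(x))
  lam <- rep(NA_real_, length(usub))
  skipped <- character(0)
  for (i in seq_along(usub)) {
    ho <- subjects == usub[i]
    ytr <- y[!ho]
    if (family == "logistic" && length(unique(encode_binary(ytr))) < 2L) {
      warning("fold for subject ", usub[i],
              " skipped: a class would be empty")
      skipped <- c(skipped, usub[i])
      next
    }
    xtr <- x[!ho, , drop = FALSE]
    xho <- x[ho, , drop = FALSE]
    if (filter_flags && !is.null(labeled$flags)) {
      frac <- colMeans(labeled$flags[!ho, , drop = FALSE])
      keep <- frac <= flag_threshold
      xtr <- xtr[, keep, drop = FALSE]
      xho <- xho[, keep, drop = FALSE]
    }
    fold_seed <- derive_seed(seed, i)
    lam[i] <- if (refit_lambda) {
      repeated_cv_lambda(xtr, ytr, family, alpha, k = k,
                         repeats = loso_repeats, seed = fold_seed,
                         n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio)$lambda
    } else lambda
    m <- fit_penalized(xtr, ytr, family, alpha, lambda = lam[i])
    scores[ho] <- predict(m, xho)
  }
  ok <- !is.na(scores)
  perf <- summarize_performance(y[ok], scores[ok], family, boundary)
  preds <- data.frame(unit_id = labeled$ids, subject = subjects,
                      truth = as.character(y), score = scores,
                      stringsAsFactors = FALSE)
  if (family == "logistic")
    preds$predicted_class <- ifelse(is.na(scores), NA,
                                    ifelse(scores > boundary, "positive",
                                           "negative"))
  structure(list(predictions = preds, metrics = perf,
                 lambda_per_fold = lam, n_folds = length(usub),
                 skipped = skipped),
            class = "loso_result")
}

summarize_performance <- function(y, score, family, boundary = 0.5) {
  if (family == "linear") r_squared(as.numeric(y), score)
  else metrics(confusion(y, score, boundary))
}

#' Independent validation of a finalized model
#'
#' Applies a model finalized on the training set only to the corresponding
#' independent validation set, and reports the regression fit (R-squared)
#' or the classification metrics at the 0.5 decision boundary.
#'
#' @param model a \code{penalized_model}.
#' @param labeled_val validation \code{labeled_set}.
#' @param boundary decision boundary for classification.
#' @return list of class \code{iv_result}: \code{predictions},
#'   \code{metrics}.
#' @export
independent_validate <- function(model, labeled_val, boundary = 0.5) {
  score <- predict(model, labeled_val$x)
  perf <- summarize_performance(labeled_val$target, score, model$family,
                                boundary)
  preds <- data.frame(unit_id = labeled_val$ids,
                      subject = labeled_val$subjects,
                      truth = as.character(labeled_val$target),
                      score = score, stringsAsFactors = FALSE)
  if (model$family == "logistic")
    preds$predicted_class <- ifelse(score > boundary, "positive", "negative")
  structure(list(predictions = preds, metrics = perf), class = "iv_result")
}
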