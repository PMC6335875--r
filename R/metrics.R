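#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2},
#' with \eqn{\bar y} taken from the evaluated set. On validation data this
#' can be negative.
#'
#' @param y observed values (>= 2, not constant).
#' @param y_hat predicted values.
#' @return list of class \code{regression_fit}: \code{observed},
#'   \code{predicted}, \code{r_squared}.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) < 2L || length(y) != length(y_hat))
    stop("`y` and `y_hat` must be aligned vectors of length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("`y` is constant; R-squared undefined")
  structure(list(observed = y, predicted = y_hat,
                 r_squared = 1 - sum((y - y_hat)^2) / ss_tot),
            class = "regression_fit")
}

#' Confusion matrix at a decision boundary
#'
#' A unit is called positive when its score strictly exceeds the boundary;
#' a score exactly at the boundary is classified negative. Scores are
#' probabilities (boundary 0.5) or raw predicted values (e.g. predicted
#' hours awake with boundary 24).
#'
#' @param truth two-class labels; a factor with levels
#'   \code{c("negative", "positive")}, or anything \code{encode_binary}
#'   accepts.
#' @param score numeric scores, aligned with \code{truth}.
#' @param boundary decision boundary (default 0.5).
#' @param type \code{"probability"} (scores must lie in \[0, 1\]) or
#'   \code{"value"}.
#' @return list of class \code{confusion_matrix}: TP, FP, FN, TN.
#' @export
confusion <- function(truth, score, boundary = 0.5,
                      type = c("probability", "value")) {
  type <- match.arg(type)
  yt <- encode_binary(truth)
  if (length(yt) != length(score)) stop("`truth` and `score` must align")
  if (type == "probability" && any(score < 0 | score > 1))
    stop("probability scores must lie in [0, 1]")
  yp <- as.numeric(score > boundary)
  structure(list(TP = sum(yt == 1 & yp == 1), FP = sum(yt == 0 & yp == 1),
                 FN = sum(yt == 1 & yp == 0), TN = sum(yt == 0 & yp == 0)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' ACC = (TP + TN) / (TP + TN + FP + FN); Sn = TP / (TP + FN);
#' Sp = TN / (TN + FP); MCC = (TP.TN - FP.FN) /
#' sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric whose denominator is zero
#' is reported as NA, never as 0.
#'
#' @param cm a \code{confusion_matrix} or a list with TP, FP, FN, TN.
#' @return list of class \code{classification_metrics}: ACC, Sn, Sp, MCC
#'   (proportions on \[0, 1\]; MCC on \[-1, 1\]).
#' @export
metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  tot <- TP + TN + FP + FN
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  structure(list(ACC = safe_div(TP + TN, tot),
                 Sn = safe_div(TP, TP + FN),
                 Sp = safe_div(TN, TN + FP),
                 MCC = if (denom > 0) (TP * TN - FP * FN) / denom
                       else NA_real_),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  # whole-percent summary formatting; machine-readable values stay exact
  cat(sprintf("ACC = %.0f%% Sn = %.0f%% Sp = %.0f%% MCC = %.2f\n",
              100 * x$ACC, 100 * x$Sn, 100 * x$Sp, x$MCC))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Standardized mean difference \eqn{d = (M_1 - M_2) / s_{pooled}} with
#' \eqn{s_{pooled} = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param g1,g2 numeric vectors (each >= 2 values).
#' @return list of class \code{effect_size}: M1, M2, s_pooled, d.
#' @export
cohens_d <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  structure(list(M1 = mean(g1), M2 = mean(g2), s_pooled = sp,
                 d = (mean(g1) - mean(g2)) / sp),
            class = "effect_size")
}

#' Pairwise Cohen's d matrix across observed time-awake levels
#'
#' Groups predicted time-awake values by their observed sampling level and
#' computes the antisymmetric matrix of pairwise Cohen's d values; levels
#' with fewer than two samples give NA rows/columns.
#'
#' @param predicted predicted time-awake values.
#' @param observed observed time-awake levels (grouping variable).
#' @return numeric matrix, levels x levels, \code{d[i, j] = -d[j, i]},
#'   zero diagonal.
#' @export
effect_size_matrix <- function(predicted, observed) {
  lev <- sort(unique(observed))
  if (length(lev) < 2L) stop("need >= 2 observed levels")
  groups <- split(predicted, factor(observed, levels = lev))
  m <- matrix(NA_real_, length(lev), length(lev),
              dimnames = list(lev, lev))
  for (i in seq_along(lev)) {
    if (length(groups[[i]]) < 2L) next
    m[i, i] <- 0
    for (j in seq_along(lev)) {
      if (i == j || length(groups[[j]]) < 2L) next
      m[i, j] <- cohens_d(groups[[i]], groups[[j]])$d
    }
  }
  m
}

#' Classify wakefulness beyond 24 hours from predicted time awake
#'
#' Positive ("awake > 24 hr") when the predicted time-awake value strictly
#' exceeds 24 hours; exactly 24 classifies negative.
#'
#' @param predicted numeric predicted time-awake values.
#' @return factor with levels \code{c("negative", "positive")}.
#' @export
classify_gt24 <- function(predicted) {
  factor(ifelse(predicted > 24, "positive", "negative"),
         levels = c("negative", "positive"))
}
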