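#' Time-awake trend test for one feature
#'
#' Within each sleep-history condition, ordinary least squares of abundance
#' on hours awake with subject fixed effects (subject-mean centering), and
#' a two-sided t test on the slope. Run vectorized over a whole matrix by
#' \code{\link{screen_features}}.
#'
#' @param values numeric vector of abundances, aligned with
#'   \code{metadata$sample_id}.
#' @param metadata sample metadata (subject_id, condition, hours_awake).
#' @return list with \code{slope} and \code{p}, each named by condition
#'   (sufficient, insufficient).
#' @export
trend_test <- function(values, metadata) {
  sc <- screen_trend(matrix(values, 1), metadata)
  list(slope = c(sufficient = sc$slope_s, insufficient = sc$slope_i),
       p = c(sufficient = sc$p_s, insufficient = sc$p_i))
}

#' Cosinor circadian test for one feature
#'
#' Regression on \eqn{\cos(2\pi h/24)} and \eqn{\sin(2\pi h/24)} of clock
#' time, after adjusting for subject fixed effects and a linear hours-awake
#' term; joint F test on the two rhythm coefficients; amplitude
#' \eqn{\sqrt{\beta_c^2 + \beta_s^2}}.
#'
#' @inheritParams trend_test
#' @return list with \code{amplitude} and \code{p}.
#' @export
circadian_test <- function(values, metadata) {
  sc <- screen_circadian(matrix(values, 1), metadata)
  list(amplitude = sc$amplitude, p = sc$p_circ)
}

#' Sleep-condition contrast for one feature
#'
#' Paired two-sided t test of subject-level condition means
#' (insufficient minus sufficient); pairing removes the trait-like subject
#' variance.
#'
#' @inheritParams trend_test
#' @return list with \code{shift} (mean paired difference) and \code{p}.
#' @export
condition_test <- function(values, metadata) {
  sc <- screen_condition(matrix(values, 1), metadata)
  list(shift = sc$shift, p = sc$p_cond)
}

#' Screen all features for the a-priori selection criteria
#'
#' Computes, per feature, the time-awake trend test within each condition,
#' the cosinor circadian test, and the paired condition contrast, plus the
#' three screening decisions at level \code{alpha_screen}.
#'
#' @param x an \code{expr_set} or features x samples matrix.
#' @param metadata sample metadata for the columns of \code{x} (screen on
#'   training samples only when used inside a pipeline).
#' @param alpha_screen significance level for the screening decisions.
#' @return data.frame of class \code{feature_screen}: feature_id, slope_s,
#'   p_s, slope_i, p_i, amplitude, p_circ, shift, p_cond, has_trend,
#'   has_circadian, has_condition_diff, in_hours_awake,
#'   in_sleep_sufficiency.
#' @export
screen_features <- function(x, metadata, alpha_screen = 0.05) {
  es <- as_expr_set(x)
  md <- metadata[match(colnames(es$values), metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("metadata is missing sample(s) present in the matrix")
  Y <- es$values
  tr <- screen_trend(Y, md)
  ci <- screen_circadian(Y, md)
  co <- screen_condition(Y, md)
  sc <- data.frame(feature_id = rownames(Y) %||% sprintf("f%d", seq_len(nrow(Y))),
                   tr, ci, co, stringsAsFactors = FALSE)
  sc <- apply_screen_decisions(sc, alpha_screen)
  attr(sc, "alpha_screen") <- alpha_screen
  class(sc) <- c("feature_screen", "data.frame")
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_screen_decisions <- function(sc, alpha) {
  trend_both <- sc$p_s < alpha & sc$p_i < alpha &
    sign(sc$slope_s) == sign(sc$slope_i)
  trend_any <- sc$p_s < alpha | sc$p_i < alpha
  sc$has_trend <- trend_both
  sc$has_circadian <- sc$p_circ < alpha
  sc$has_condition_diff <- sc$p_cond < alpha
  sc$in_hours_awake <- trend_both & !sc$has_circadian & !sc$has_condition_diff
  sc$in_sleep_sufficiency <- sc$has_condition_diff & !sc$has_circadian &
    !trend_any
  sc
}

# vectorized within-condition OLS of Y rows on hours_awake with subject
# fixed effects; returns slopes and two-sided t-test p values per condition
screen_trend <- function(Y, md) {
  out <- list()
  for (cond in c("sufficient", "insufficient")) {
    idx <- which(md$condition == cond)
    if (length(idx) < 3L) stop("need >= 3 timepoints per condition")
    t_aw <- md$hours_awake[idx]
    subj <- factor(md$subject_id[idx])
    e <- t_aw - ave(t_aw, subj)
    see <- sum(e^2)
    if (see <= .Machine$double.eps * length(e) * max(1, mean(t_aw)^2))
      stop("degenerate design: hours_awake constant within subjects (",
           cond, ")")
    Yc <- Y[, idx, drop = FALSE]
    Yc <- Yc - t(apply(Yc, 1, function(v) ave(v, subj)))
    slope <- drop(Yc %*% e) / see
    res <- Yc - outer(slope, e)
    df <- length(idx) - nlevels(subj) - 1L
    if (df < 1L) stop("not enough residual degrees of freedom (", cond, ")")
    s2 <- rowSums(res^2) / df
    tt <- slope / sqrt(pmax(s2, .Machine$double.xmin) / see)
    p <- 2 * pt(-abs(tt), df)
    suffix <- if (cond == "sufficient") "s" else "i"
    out[[paste0("slope_", suffix)]] <- slope
    out[[paste0("p_", suffix)]] <- p
  }
  as.data.frame(out)
}

# vectorized cosinor: rhythm columns residualized on subject + hours_awake
# (Frisch-Waugh), joint F test on the two rhythm coefficients
screen_circadian <- function(Y, md) {
  span <- diff(range(md$clock_time %% 24))
  if (span < 12 || length(unique(md$clock_time %% 24)) < 3L)
    stop("clock times must span at least half a cycle")
  ang <- 2 * pi * md$clock_time / 24
  R <- cbind(cos = cos(ang), sin = sin(ang))
  M0 <- stats::model.matrix(~ factor(md$subject_id) + md$hours_awake)
  q0 <- qr(M0)
  Rp <- R - qr.fitted(q0, R)  # residualize the rhythm columns on M0
  Yp <- t(Y) - qr.fitted(q0, t(Y))
  qr_r <- qr(Rp)
  if (qr_r$rank < 2L) stop("collinear regressors in the cosinor fit")
  B <- qr.coef(qr_r, Yp)              # 2 x features
  fit <- qr.fitted(qr_r, Yp)
  res <- Yp - fit
  df1 <- nrow(Yp) - q0$rank - 2L
  if (df1 < 1L) stop("not enough residual degrees of freedom for cosinor")
  rss1 <- colSums(res^2)
  rss0 <- colSums(Yp^2)
  Fstat <- ((rss0 - rss1) / 2) / pmax(rss1 / df1, .Machine$double.xmin)
  p <- pf(Fstat, 2, df1, lower.tail = FALSE)
  data.frame(amplitude = sqrt(B[1, ]^2 + B[2, ]^2), p_circ = p)
}

# vectorized paired t test of subject-level condition means
screen_condition <- function(Y, md) {
  key <- paste(md$subject_id, md$condition)
  means <- t(rowsum(t(Y), key) / as.vector(table(key)[sort(unique(key))]))
  subj <- unique(md$subject_id)
  have_both <- subj[paste(subj, "sufficient") %in% colnames(means) &
                    paste(subj, "insufficient") %in% colnames(means)]
  if (length(have_both) < 3L)
    stop("paired condition test needs >= 3 complete subject pairs")
  D <- means[, paste(have_both, "insufficient"), drop = FALSE] -
       means[, paste(have_both, "sufficient"), drop = FALSE]
  n <- ncol(D)
  shift <- rowMeans(D)
  sdd <- sqrt(rowSums((D - shift)^2) / (n - 1))
  tt <- shift / pmax(sdd / sqrt(n), .Machine$double.xmin)
  data.frame(shift = shift, p_cond = 2 * pt(-abs(tt), n - 1))
}

#' Select an a-priori feature set from a screen
#'
#' The "hours awake" set contains features with a significant, sign-
#' concordant time-awake trend in both sleep-history conditions, no
#' significant circadian modulation, and no significant condition
#' difference. The "sleep sufficiency" set contains features with a
#' significant condition difference, no circadian modulation, and no trend
#' in either condition. The two sets are disjoint by construction, and an
#' empty result is allowed.
#'
#' @param screen a \code{feature_screen} from \code{\link{screen_features}}.
#' @param set_name \code{"hours_awake"} or \code{"sleep_sufficiency"}.
#' @param alpha_screen significance level; decisions are recomputed from
#'   the stored p-values at this level.
#' @return character vector of selected feature ids.
#' @export
select_a_priori <- function(screen,
                            set_name = c("hours_awake", "sleep_sufficiency"),
                            alpha_screen = 0.05) {
  set_name <- match.arg(set_name)
  sc <- apply_screen_decisions(as.data.frame(screen), alpha_screen)
  col <- if (set_name == "hours_awake") "in_hours_awake"
         else "in_sleep_sufficiency"
  out <- sc$feature_id[sc[[col]]]
  if (!length(out))
    message("a-priori set '", set_name, "' is empty at alpha = ",
            alpha_screen)
  out
}

#' Write a feature screen as TSV
#' @param screen a \code{feature_screen}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_screen <- function(screen, path) {
  write_tsv(as.data.frame(screen), path)
}
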