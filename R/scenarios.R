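#' Benchmark scenarios for end-to-end pipeline validation
#'
#' Three fixed synthetic study designs exercise the pipeline against known
#' ground truth. Their generator settings are part of the scenario
#' definition (see the methods vignette for the sizing arguments) and are
#' not tuning knobs.
#'
#' \describe{
#'   \item{\code{scenario_tuning}}{Panel recovery under lambda tuning: ten
#'     informative time-awake trend features among 2,000 (per-feature
#'     standardized trend effect 1.5 over the sampling range), 18 subjects.
#'     Repeated-CV elastic net should recover most true features with few
#'     null features in the panel.}
#'   \item{\code{scenario_acute}}{Acute sleep loss, between-subject: 36
#'     subjects split UPUS, 30 trend features sized so the Bayes error of
#'     the #1-vs-#9 contrast is below 5\%; independent validation should
#'     approach that ceiling and agree with LOSO-CV.}
#'   \item{\code{scenario_chronic}}{Chronic sleep insufficiency: condition
#'     effect (0.15 log2 units) far below the trait sd (1.0), so
#'     between-subject classification from one sample is near-hopeless
#'     while the within-subject visit difference isolates the effect.}
#'   \item{\code{scenario_confounded_opus}}{Labels carry no condition
#'     signal at all; a penalized model can only memorize subjects. The
#'     OPUS split then anti-predicts validation labels (negative MCC)
#'     while subject-disjoint LOSO-CV stays at chance.}
#' }
#'
#' @param seed integer seed controlling every random draw in the scenario.
#' @param repeats lambda-tuning repeats for the full training set.
#' @param loso_repeats lambda-tuning repeats inside LOSO folds.
#' @return a list of scenario-specific summary quantities (see each
#'   function's Value section).
#' @name scenarios
NULL

#' @rdname scenarios
#' @return \code{scenario_tuning}: list with \code{panel},
#'   \code{n_true_selected} (of 10), \code{null_fraction} of the panel,
#'   \code{lambda}.
#' @export
scenario_tuning <- function(seed = 1L, repeats = 20) {
  # per-feature standardized trend effect = a * sd(hours awake) / sd(noise)
  tp <- default_timepoints()
  sd_t <- sqrt(mean((tp$hours_awake - mean(tp$hours_awake))^2))
  trait_sd <- 0.5; noise_sd <- 0.4
  a <- 1.5 * sqrt(trait_sd^2 + noise_sd^2) / sd_t
  ch <- generate_cohort(synthetic_config(
    n_subjects = 12, n_features = 2000, n_trend = 10, n_circadian = 0,
    n_condition = 0, n_mixed = 0, trend_slope = a, trait_sd = trait_sd,
    noise_sd = noise_sd, flag_rate = 0, seed = seed))
  lab <- assemble_variable(percentile_normalize(ch$expression),
                           ch$metadata, "time_awake", "between")
  cv <- repeated_cv_lambda(lab$x, lab$target, "linear", alpha = 0.5,
                           k = 10, repeats = repeats,
                           seed = derive_seed(seed, 7L), n_lambda = 50,
                           lambda_min_ratio = 0.01)
  model <- finalize_model(lab$x, lab$target, "linear", 0.5, cv)
  panel <- nonzero_panel(model)
  true_ids <- ch$truth$feature_id[ch$truth$class == "trend"]
  list(panel = panel,
       n_true_selected = sum(true_ids %in% panel),
       null_fraction = if (length(panel))
         mean(!(panel %in% true_ids)) else 0,
       lambda = cv$lambda)
}

# shared crossover cohort for the acute and chronic scenarios
sleep_debt_cohort <- function(seed, n_features = 2000) {
  generate_cohort(synthetic_config(
    n_subjects = 36, n_features = n_features, n_trend = 30,
    n_circadian = 30, n_condition = 40, n_mixed = 0,
    trend_slope = 0.03, circadian_amplitude = 0.5,
    condition_effect = 0.15, trait_sd = 1.0, noise_sd = 0.25,
    flag_rate = 0.01, seed = seed))
}

# one variable through the split -> filter -> tune -> finalize -> LOSO ->
# IV chain; returns both performance summaries
run_variable <- function(ch, variable, mode, seed, repeats, loso_repeats,
                         sample_index = NULL, alpha = 0.5,
                         apriori_set = NULL) {
  es <- percentile_normalize(expr_set(ch$expression, ch$flags))
  md <- ch$metadata
  # visit-difference classification additionally balances the split on
  # clinic-visit order, so both sides carry both change directions
  balance <- "sex"
  if (variable == "sleep_change") {
    md <- add_visit1_condition(md)
    balance <- c("sex", "visit1_condition")
  }
  sp <- split_upus(md, balance = balance, seed = derive_seed(seed, 2L))
  tr <- subset_samples(es, ch$metadata, sp$train_sample_ids)
  va <- subset_samples(es, ch$metadata, sp$validation_sample_ids)
  filt <- filter_flagged(tr$expression, list(va$expression))
  lab_tr <- assemble_variable(filt$train, tr$metadata, variable, mode,
                              sample_index = sample_index)
  lab_va <- assemble_variable(filt$apply_to[[1]], va$metadata, variable,
                              mode, sample_index = sample_index)
  if (!is.null(apriori_set)) {
    # screen on the training side only, as the pipeline does
    sc <- screen_features(filt$train, tr$metadata)
    feats <- select_a_priori(sc, apriori_set)
    feats <- intersect(feats, colnames(lab_tr$x))
    if (length(feats) < 2L)
      stop("a-priori set too small (", length(feats), " features)")
    lab_tr$x <- lab_tr$x[, feats, drop = FALSE]
    lab_va$x <- lab_va$x[, feats, drop = FALSE]
  }
  cv <- repeated_cv_lambda(lab_tr$x, lab_tr$target, lab_tr$family,
                           alpha = alpha, k = 10, repeats = repeats,
                           seed = derive_seed(seed, 3L), n_lambda = 50,
                           lambda_min_ratio = 0.01)
  model <- finalize_model(lab_tr$x, lab_tr$target, lab_tr$family, alpha,
                          cv)
  loso <- loso_cv(lab_tr, alpha = alpha, k = 10,
                  loso_repeats = loso_repeats,
                  seed = derive_seed(seed, 4L), n_lambda = 50,
                  lambda_min_ratio = 0.01)
  iv <- independent_validate(model, lab_va)
  list(model = model, loso = loso$metrics, iv = iv$metrics,
       panel = nonzero_panel(model))
}

#' @rdname scenarios
#' @return \code{scenario_acute}: list with \code{iv_acc},
#'   \code{loso_acc}, \code{gap}, \code{panel_size}.
#' @export
scenario_acute <- function(seed = 1L, repeats = 20, loso_repeats = 5) {
  ch <- sleep_debt_cohort(derive_seed(seed, 1L))
  res <- run_variable(ch, "acute_loss", "between", seed, repeats,
                      loso_repeats)
  list(iv_acc = res$iv$ACC, loso_acc = res$loso$ACC,
       gap = abs(res$loso$ACC - res$iv$ACC),
       panel_size = length(res$panel))
}

#' @rdname scenarios
#' @return \code{scenario_chronic}: list with \code{between_iv_acc} and
#'   \code{within_iv_acc}.
#' @export
scenario_chronic <- function(seed = 1L, repeats = 20, loso_repeats = 5) {
  ch <- sleep_debt_cohort(derive_seed(seed, 1L))
  # between-subject: elastic net over all features, as in the headline
  # chronic comparison; within-subject change detection: ridge on the
  # a-priori sleep-sufficiency set, the study's best-performing route
  between <- run_variable(ch, "chronic_insufficiency", "between", seed,
                          repeats, loso_repeats)
  within <- run_variable(ch, "sleep_change", "within", seed, repeats,
                         loso_repeats, alpha = 0,
                         apriori_set = "sleep_sufficiency")
  list(between_iv_acc = between$iv$ACC, within_iv_acc = within$iv$ACC)
}

#' @rdname scenarios
#' @return \code{scenario_confounded_opus}: list with \code{opus_iv_mcc}
#'   and \code{upus_loso_mcc}.
#' @export
scenario_confounded_opus <- function(seed = 1L, repeats = 5,
                                     loso_repeats = 2) {
  # no condition effect at all: the only learnable structure is the
  # trait-like subject signature
  ch <- generate_cohort(synthetic_config(
    n_subjects = 12, n_features = 500, n_trend = 0, n_circadian = 0,
    n_condition = 0, n_mixed = 0, trait_sd = 1.0, noise_sd = 0.25,
    flag_rate = 0, seed = derive_seed(seed, 1L)))
  es <- percentile_normalize(expr_set(ch$expression, ch$flags))
  label_by_condition <- function(values, md) {
    structure(list(
      x = t(values), target = factor(
        ifelse(md$condition == "insufficient", "positive", "negative"),
        levels = c("negative", "positive")),
      ids = md$sample_id, subjects = md$subject_id,
      variable = "condition_all_samples", mode = "between",
      family = "logistic"),
      class = "labeled_set")
  }
  # OPUS: one condition per subject in training, the other in validation
  sp_o <- split_opus(ch$metadata, seed = derive_seed(seed, 2L))
  tr <- subset_samples(es, ch$metadata, sp_o$train_sample_ids)
  va <- subset_samples(es, ch$metadata, sp_o$validation_sample_ids)
  lab_tr <- label_by_condition(tr$expression$values, tr$metadata)
  lab_va <- label_by_condition(va$expression$values, va$metadata)
  cv <- repeated_cv_lambda(lab_tr$x, lab_tr$target, "logistic", 0.5,
                           k = 10, repeats = repeats,
                           seed = derive_seed(seed, 3L), n_lambda = 50,
                           lambda_min_ratio = 0.01)
  model <- finalize_model(lab_tr$x, lab_tr$target, "logistic", 0.5, cv)
  iv <- independent_validate(model, lab_va)
  # UPUS: subject-disjoint training, LOSO-CV stays at chance
  sp_u <- split_upus(ch$metadata, seed = derive_seed(seed, 4L))
  tru <- subset_samples(es, ch$metadata, sp_u$train_sample_ids)
  lab_u <- label_by_condition(tru$expression$values, tru$metadata)
  loso <- loso_cv(lab_u, alpha = 0.5, k = 10,
                  loso_repeats = loso_repeats,
                  seed = derive_seed(seed, 5L), n_lambda = 50,
                  lambda_min_ratio = 0.01)
  list(opus_iv_mcc = iv$metrics$MCC, upus_loso_mcc = loso$metrics$MCC)
}
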