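#' Default desk-scale experiment configuration
#'
#' A complete run configuration for the experiment grid: synthetic cohort
#' source, the sleep-debt variables, partition schemes, assessment modes,
#' feature inputs and penalized methods, plus tuning knobs. Any element can
#' be overridden; the configuration can also be supplied as a YAML file to
#' \code{\link{run_experiment}}.
#'
#' @param ... overrides for the defaults.
#' @return named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    cohort = list(source = "synthetic",
                  n_subjects = 12, n_features = 2000,
                  n_trend = 50, n_circadian = 50, n_condition = 50,
                  n_mixed = 10),
    variables = c("time_awake", "acute_loss", "chronic_insufficiency"),
    schemes = "UPUS",
    modes = c("between", "within"),
    feature_inputs = c("all_features", "a_priori"),
    methods = c("elastic_net", "ridge"),
    alpha_screen = 0.05,
    k = 10, repeats = 20, loso_repeats = 5,
    n_lambda = 100, lambda_min_ratio = 0.01,
    flag_threshold = 0.10,
    seed = 1L,
    output_dir = NULL)
  utils::modifyList(cfg, list(...))
}

method_alpha <- function(method) {
  switch(method, elastic_net = 0.5, ridge = 0,
         stop("unknown method: ", method))
}

# which a-priori set feeds which variable
apriori_set_for <- function(variable) {
  if (variable %in% c("time_awake", "gt24", "acute_loss")) "hours_awake"
  else "sleep_sufficiency"
}

#' Run the full biomarker-discovery experiment grid
#'
#' Mirrors the study workflow end to end for every requested combination of
#' variable, partition scheme, assessment mode, feature input and penalized
#' method: generate (or read) the cohort, percentile-normalize, split,
#' remove features flagged in more than the threshold fraction of
#' *training* samples, assemble the labeled sets, optionally restrict to an
#' a-priori screened feature list (screened on training samples only), tune
#' lambda by repeated stratified k-fold CV, finalize the model on the full
#' training side, and assess by LOSO-CV and independent validation.
#' Outputs (metrics.tsv, per-combination panels and predictions, and a
#' manifest with every derived seed) reproduce exactly under the same
#' configuration.
#'
#' @param config a list from \code{\link{default_run_config}}, or the path
#'   to a YAML file with the same structure.
#' @return invisibly, a list with \code{metrics} (one row per combination),
#'   \code{results} (per-combination details), \code{manifest}, and
#'   \code{output_dir} (NULL if no directory was requested).
#' @export
run_experiment <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # stage 1: cohort
  if (identical(cfg$cohort$source, "synthetic")) {
    sc_args <- cfg$cohort[setdiff(names(cfg$cohort), "source")]
    sc_args$seed <- derive_seed(cfg$seed, 1L)
    cohort <- generate_cohort(do.call(synthetic_config, sc_args))
    es <- expr_set(cohort$expression, cohort$flags)
    md <- cohort$metadata
  } else {
    loaded <- read_cohort(cfg$cohort$path)
    es <- loaded$expression
    md <- loaded$metadata
  }
  es <- percentile_normalize(es)

  grid <- expand.grid(variable = cfg$variables, scheme = cfg$schemes,
                      mode = cfg$modes, feature_input = cfg$feature_inputs,
                      method = cfg$methods, stringsAsFactors = FALSE)
  # chronic insufficiency has no within-subject mode; sleep_change no between
  grid <- grid[!(grid$variable == "chronic_insufficiency" &
                   grid$mode == "within"), ]
  grid <- grid[!(grid$variable == "sleep_change" & grid$mode == "between"), ]
  # ridge is the a-priori-panel method; pair it with all features only on
  # explicit request
  if (!isTRUE(cfg$ridge_on_all_features))
    grid <- grid[!(grid$method == "ridge" &
                     grid$feature_input == "all_features"), ]
  grid <- grid[!duplicated(grid[c("variable", "scheme", "feature_input",
                                  "method",
                                  "mode")]), ]

  rows <- list(); details <- list(); manifest_runs <- list()
  for (g in seq_len(nrow(grid))) {
    combo <- grid[g, ]
    res <- tryCatch(
      run_combination(es, md, combo, cfg, combo_seed = derive_seed(cfg$seed,
                                                                   100 + g)),
      error = function(e) e)
    tag <- paste(combo$variable, combo$scheme, combo$mode,
                 combo$feature_input, combo$method, sep = "/")
    if (inherits(res, "error")) {
      warning("combination ", tag, " failed: ", conditionMessage(res))
      manifest_runs[[tag]] <- list(status = "error",
                                   message = conditionMessage(res))
      next
    }
    rows[[tag]] <- res$row
    details[[tag]] <- res
    manifest_runs[[tag]] <- list(status = "ok", seed = res$seed,
                                 lambda = res$lambda,
                                 panel_size = length(res$panel))
    if (!is.null(out_dir)) {
      safe <- gsub("/", "_", tag)
      write_model(res$model, file.path(out_dir, paste0("model_", safe,
                                                       ".tsv")))
      writeLines(res$panel, file.path(out_dir, paste0("panel_", safe,
                                                      ".txt")))
      write_tsv(res$iv$predictions,
                file.path(out_dir, paste0("predictions_", safe, ".tsv")))
    }
  }
  metrics_df <- do.call(rbind, rows)
  manifest <- list(package = "sleepmarkr",
                   version = as.character(utils::packageVersion("sleepmarkr")),
                   r_version = as.character(getRversion()),
                   master_seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "output_dir")],
                   runs = manifest_runs)
  if (!is.null(out_dir)) {
    write_tsv(metrics_df, file.path(out_dir, "metrics.tsv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(list(metrics = metrics_df, results = details,
                 manifest = manifest, output_dir = out_dir))
}

run_combination <- function(es, md, combo, cfg, combo_seed) {
  scheme_seed <- derive_seed(cfg$seed, 2L)  # shared across combinations
  # sleep_change splits additionally balance on clinic-visit order so both
  # sides carry both change directions
  balance <- "sex"
  if (combo$variable == "sleep_change") {
    md <- add_visit1_condition(md)
    balance <- c("sex", "visit1_condition")
  }
  split <- if (combo$scheme == "UPUS")
    split_upus(md, balance = balance, seed = scheme_seed)
  else split_opus(md, seed = scheme_seed)

  tr <- subset_samples(es, md, split$train_sample_ids)
  va <- subset_samples(es, md, split$validation_sample_ids)
  # flagged-feature removal decided on the training side only
  filt <- filter_flagged(tr$expression, list(va$expression),
                         threshold = cfg$flag_threshold)
  tr$expression <- filt$train
  va$expression <- filt$apply_to[[1]]

  # gt24 is classified by thresholding the predicted time-awake value at
  # 24 hr, so its model is the time_awake regression
  is_gt24 <- combo$variable == "gt24"
  fit_variable <- if (is_gt24) "time_awake" else combo$variable
  lab_tr <- assemble_variable(tr$expression, tr$metadata, fit_variable,
                              combo$mode)
  lab_va <- assemble_variable(va$expression, va$metadata, fit_variable,
                              combo$mode)

  if (combo$feature_input == "a_priori") {
    screen <- screen_features(tr$expression, tr$metadata,
                              alpha_screen = cfg$alpha_screen)
    feats <- select_a_priori(screen, apriori_set_for(combo$variable),
                             alpha_screen = cfg$alpha_screen)
    if (length(feats) < 2L)
      stop("a-priori set too small (", length(feats), " features)")
    lab_tr$x <- lab_tr$x[, feats, drop = FALSE]
    lab_va$x <- lab_va$x[, feats, drop = FALSE]
  }

  alpha <- method_alpha(combo$method)
  cv <- repeated_cv_lambda(lab_tr$x, lab_tr$target, lab_tr$family,
                           alpha = alpha, k = cfg$k, repeats = cfg$repeats,
                           seed = derive_seed(combo_seed, 1L),
                           n_lambda = cfg$n_lambda,
                           lambda_min_ratio = cfg$lambda_min_ratio)
  model <- finalize_model(lab_tr$x, lab_tr$target, lab_tr$family,
                          alpha = alpha, cv = cv)
  loso <- loso_cv(lab_tr, alpha = alpha, k = cfg$k,
                  loso_repeats = cfg$loso_repeats,
                  seed = derive_seed(combo_seed, 2L),
                  n_lambda = cfg$n_lambda,
                  lambda_min_ratio = cfg$lambda_min_ratio)
  iv <- independent_validate(model, lab_va)
  if (is_gt24) {
    # reinterpret predicted hours awake as a two-class call at 24 hr
    gt24_metrics <- function(hours, score) {
      ok <- !is.na(score)
      metrics(confusion(classify_gt24(hours[ok]), score[ok], boundary = 24,
                        type = "value"))
    }
    loso$metrics <- gt24_metrics(lab_tr$target, loso$predictions$score)
    iv$metrics <- gt24_metrics(lab_va$target, iv$predictions$score)
  }

  fmt <- function(m) {
    if (inherits(m, "regression_fit"))
      c(ACC = NA_real_, Sn = NA_real_, Sp = NA_real_, MCC = NA_real_,
        R2 = m$r_squared)
    else c(ACC = m$ACC, Sn = m$Sn, Sp = m$Sp, MCC = m$MCC, R2 = NA_real_)
  }
  lm_ <- fmt(loso$metrics); iv_ <- fmt(iv$metrics)
  row <- data.frame(variable = combo$variable, scheme = combo$scheme,
                    mode = combo$mode, feature_input = combo$feature_input,
                    method = combo$method,
                    n_train = nrow(lab_tr$x), n_val = nrow(lab_va$x),
                    panel_size = length(nonzero_panel(model)),
                    lambda = cv$lambda,
                    loso_ACC = lm_["ACC"], loso_Sn = lm_["Sn"],
                    loso_Sp = lm_["Sp"], loso_MCC = lm_["MCC"],
                    loso_R2 = lm_["R2"],
                    iv_ACC = iv_["ACC"], iv_Sn = iv_["Sn"],
                    iv_Sp = iv_["Sp"], iv_MCC = iv_["MCC"],
                    iv_R2 = iv_["R2"],
                    stringsAsFactors = FALSE)
  rownames(row) <- NULL
  list(row = row, model = model, panel = nonzero_panel(model), cv = cv,
       loso = loso, iv = iv, split = split, seed = combo_seed,
       lambda = cv$lambda)
}

#' Read a GEO Series Matrix file
#'
#' Minimal reader for the plain-text GEO Series Matrix format: sample
#' annotation lines start with \code{!}, and the expression table sits
#' between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end}. Metadata fields requiring study
#' knowledge (hours awake, sample index, condition) are left to a
#' user-supplied mapping and returned as a skeleton.
#'
#' @param path series-matrix file.
#' @return list with \code{expression} (features x samples matrix) and
#'   \code{annotation} (data.frame skeleton, one row per sample).
#' @export
load_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("malformed series matrix: missing !series_matrix_table_begin/end")
  tab <- utils::read.delim(text = lines[(b + 1):(e - 1)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  colnames(m) <- gsub('^"|"$', "", colnames(m))
  ann_lines <- grep("^!Sample_", lines, value = TRUE)
  ann <- list(sample_id = colnames(m))
  for (l in ann_lines) {
    parts <- strsplit(l, "\t")[[1]]
    key <- sub("^!Sample_", "", parts[1])
    vals <- gsub('^"|"$', "", parts[-1])
    if (length(vals) == ncol(m) && !key %in% names(ann)) ann[[key]] <- vals
  }
  annotation <- as.data.frame(ann, stringsAsFactors = FALSE)
  annotation$subject_id <- NA_character_
  annotation$condition <- NA_character_
  annotation$sample_index <- NA_integer_
  annotation$hours_awake <- NA_real_
  list(expression = m, annotation = annotation)
}
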