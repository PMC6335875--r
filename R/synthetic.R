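#' Default constant-routine sampling schedule
#'
#' Ten three-hourly samples per visit: sample #1 at 7.5 hr awake (clock time
#' 15.5 h, i.e. mid-afternoon, 7-8 hr after scheduled wake) through sample
#' #10 at 34.5 hr awake. Clock time advances with time awake and wraps at
#' 24 h, so sample #9 (24 h later than #1) falls at the same clock time as
#' sample #1 -- the circadian/homeostatic confound of a real constant
#' routine.
#'
#' @return data.frame with columns \code{sample_index}, \code{hours_awake},
#'   \code{clock_time}.
#' @export
default_timepoints <- function() {
  k <- 0:9
  data.frame(sample_index = k + 1L,
             hours_awake = 7.5 + 3 * k,
             clock_time = (15.5 + 3 * k) %% 24)
}

#' Configuration for a synthetic crossover sleep-debt cohort
#'
#' Defines the generative model of a two-visit (sufficient vs insufficient
#' sleep history) crossover cohort sampled through extended wakefulness.
#' Feature classes: \code{trend} (linear in hours awake), \code{circadian}
#' (24-h cosine in clock time), \code{condition} (sleep-history shift),
#' \code{mixed} (trend + condition), remainder null.
#'
#' @param n_subjects number of subjects (two visits each).
#' @param n_features total number of expression features.
#' @param n_trend,n_circadian,n_condition,n_mixed feature class counts; the
#'   sum must not exceed \code{n_features}.
#' @param trend_slope absolute time-awake slope, log2 units per hour.
#' @param circadian_amplitude cosine amplitude, log2 units.
#' @param condition_effect absolute insufficient-vs-sufficient shift, log2
#'   units.
#' @param trait_sd sd of the subject random effect (drawn once per feature
#'   x subject, shared across both visits), log2 units.
#' @param noise_sd measurement noise sd, log2 units.
#' @param flag_rate per-measurement probability of a quality flag.
#' @param timepoints data.frame as \code{\link{default_timepoints}}.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_subjects = 36, n_features = 20000,
                             n_trend = 300, n_circadian = 300,
                             n_condition = 300, n_mixed = 100,
                             trend_slope = 0.02, circadian_amplitude = 0.5,
                             condition_effect = 0.3, trait_sd = 1.0,
                             noise_sd = 0.4, flag_rate = 0.01,
                             timepoints = default_timepoints(), seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_features = n_features,
              n_trend = n_trend, n_circadian = n_circadian,
              n_condition = n_condition, n_mixed = n_mixed,
              trend_slope = trend_slope,
              circadian_amplitude = circadian_amplitude,
              condition_effect = condition_effect, trait_sd = trait_sd,
              noise_sd = noise_sd, flag_rate = flag_rate,
              timepoints = timepoints, seed = seed)
  for (f in c("n_subjects", "n_features", "n_trend", "n_circadian",
              "n_condition", "n_mixed")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop(sprintf("`%s` must be a non-negative integer", f))
  }
  if (cfg$n_trend + cfg$n_circadian + cfg$n_condition + cfg$n_mixed >
      cfg$n_features)
    stop("feature class counts exceed `n_features`")
  if (cfg$n_subjects < 1) stop("`n_subjects` must be >= 1")
  for (f in c("trend_slope", "circadian_amplitude", "condition_effect",
              "trait_sd", "noise_sd", "flag_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be finite and non-negative", f))
  }
  if (cfg$flag_rate > 1) stop("`flag_rate` must not exceed 1")
  tp <- cfg$timepoints
  if (!is.data.frame(tp) ||
      !all(c("sample_index", "hours_awake", "clock_time") %in% names(tp)) ||
      nrow(tp) < 1L || anyDuplicated(tp$sample_index))
    stop("`timepoints` must have unique sample_index, hours_awake, clock_time")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic crossover cohort
#'
#' For subject \eqn{s}, condition \eqn{c}, timepoint with hours awake
#' \eqn{t} and clock time \eqn{h}, feature \eqn{g}:
#' \deqn{y = \mu_g + u_{g,s} + a_g t + b_g \cos(2\pi (h - \phi_g)/24)
#'   + \delta_g 1[c = insufficient] + \epsilon}
#' with the trait effect \eqn{u_{g,s} \sim N(0, \tau_g^2)} drawn once per
#' (feature, subject) and shared across both visits -- the "trait-like"
#' between-subject structure that makes single-sample classification hard
#' and within-subject differencing effective. Half the subjects (rounded
#' down) visit sufficient-sleep first; sexes alternate across subjects.
#' Each measurement is independently quality-flagged with probability
#' \code{flag_rate}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{synthetic_cohort} with \code{expression}
#'   (features x samples log2 matrix), \code{flags} (same shape, 0/1),
#'   \code{metadata} (one row per sample), and \code{truth} (per-feature
#'   class and realized generative parameters).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    ns <- cfg$n_subjects; nf <- cfg$n_features
    tp <- cfg$timepoints; nt <- nrow(tp)
    feat_ids <- sprintf("f%05d", seq_len(nf))
    classes <- rep("null", nf)
    idx <- 0L
    for (cl in c("trend", "circadian", "condition", "mixed")) {
      k <- cfg[[paste0("n_", cl)]]
      if (k > 0) classes[idx + seq_len(k)] <- cl
      idx <- idx + k
    }
    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    a <- ifelse(classes %in% c("trend", "mixed"),
                cfg$trend_slope * sgn(nf), 0)
    b <- ifelse(classes == "circadian", cfg$circadian_amplitude, 0)
    phi <- runif(nf, 0, 24)
    phi[b == 0] <- 0
    delta <- ifelse(classes %in% c("condition", "mixed"),
                    cfg$condition_effect * sgn(nf), 0)
    mu <- rnorm(nf, 8, 2)
    tau <- rep(cfg$trait_sd, nf)

    subj_ids <- sprintf("sub%02d", seq_len(ns))
    sex <- rep(c("M", "F"), length.out = ns)
    # visit order: first half sufficient -> insufficient, rest reversed
    suff_first <- seq_len(ns) <= ns %/% 2
    meta <- do.call(rbind, lapply(seq_len(ns), function(s) {
      conds <- if (suff_first[s]) c("sufficient", "insufficient")
               else c("insufficient", "sufficient")
      do.call(rbind, lapply(1:2, function(v) {
        data.frame(sample_id = sprintf("%s_%s_%02d", subj_ids[s],
                                       substr(conds[v], 1, 4),
                                       tp$sample_index),
                   subject_id = subj_ids[s], sex = sex[s],
                   condition = conds[v], visit = v,
                   sample_index = tp$sample_index,
                   hours_awake = tp$hours_awake,
                   clock_time = tp$clock_time,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(meta) <- NULL

    m <- nrow(meta)
    # trait effects: features x subjects, shared across the two visits
    u <- matrix(rnorm(nf * ns, 0, 1), nf, ns) * tau
    subj_col <- match(meta$subject_id, subj_ids)
    base <- mu +
      outer(a, meta$hours_awake) +
      b * cos(2 * pi * sweep(matrix(meta$clock_time, nf, m, byrow = TRUE),
                             1, phi, "-") / 24) +
      outer(delta, as.numeric(meta$condition == "insufficient"))
    values <- base + u[, subj_col] +
      matrix(rnorm(nf * m, 0, cfg$noise_sd), nf, m)
    dimnames(values) <- list(feat_ids, meta$sample_id)
    flags <- matrix(rbinom(nf * m, 1L, cfg$flag_rate), nf, m,
                    dimnames = dimnames(values))

    truth <- data.frame(feature_id = feat_ids, class = classes,
                        a_g = a, b_g = b, phi_g = phi, delta_g = delta,
                        mu_g = mu, tau_g = tau, stringsAsFactors = FALSE)
    structure(list(expression = values, flags = flags, metadata = meta,
                   truth = truth, config = cfg),
              class = "synthetic_cohort")
  })
}

#' Write a cohort to the on-disk TSV layout
#'
#' Emits \code{expression.tsv} (feature_id + one column per sample),
#' \code{flags.tsv} (same shape, 0/1), \code{samples.tsv} (design metadata)
#' and \code{truth.tsv} (per-feature generative labels), LF line endings,
#' 17 significant digits, round-trippable through the package readers.
#'
#' @param cohort a \code{synthetic_cohort} (or a list with the same fields).
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
cohort_to_files <- function(cohort, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             flags = file.path(dir, "flags.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(cohort$expression, paths["expression"])
  write_matrix_tsv(cohort$flags, paths["flags"], integer = TRUE)
  write_tsv(cohort$metadata, paths["samples"])
  write_tsv(cohort$truth, paths["truth"])
  paths
}

# matrix writer: first column feature_id, LF endings, full precision
write_matrix_tsv <- function(x, path, integer = FALSE) {
  fmt <- if (integer) function(v) sprintf("%d", as.integer(v))
         else function(v) sprintf("%.17g", v)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con,
             sep = "\n")
  body <- vapply(seq_len(nrow(x)),
                 function(i) paste(c(rownames(x)[i], fmt(x[i, ])),
                                   collapse = "\t"),
                 character(1))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con,
               sep = "\n")
  invisible(path)
}
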