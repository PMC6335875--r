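#' Subject-disjoint (UPUS) training/validation split
#'
#' "Unique participants and unique samples": every sample of a subject goes
#' to the same side, subjects are assigned to sides by a stratified random
#' draw within each balancing stratum (default: sex), so participant
#' characteristics stay balanced across sides. A stratum with a single
#' subject is assigned to training with a warning.
#'
#' @param metadata sample metadata.
#' @param fraction fraction of subjects per stratum assigned to training.
#' @param balance character vector of metadata columns defining strata.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return object of class \code{split_pair} with train/validation sample
#'   and subject ids.
#' @export
split_upus <- function(metadata, fraction = 0.5, balance = "sex", seed = 1L) {
  subj <- unique(metadata[, c("subject_id", intersect(balance,
                                                      names(metadata))),
                          drop = FALSE])
  strata <- if (length(balance) && all(balance %in% names(subj)))
    interaction(subj[balance], drop = TRUE)
  else factor(rep("all", nrow(subj)))
  # per-stratum training counts: floor everywhere, then hand out the
  # remainders (largest fractional part first) until the overall fraction
  # is met exactly
  sizes <- table(strata)
  multi <- sizes >= 2L
  base <- floor(as.numeric(sizes) * fraction)
  target <- round(sum(sizes[multi]) * fraction)
  extra <- rep(0L, length(sizes))
  want <- order(as.numeric(sizes) * fraction - base, decreasing = TRUE)
  want <- want[multi[want]]
  need <- max(0L, target - sum(base[multi]))
  if (need > 0L) extra[utils::head(want, need)] <- 1L
  n_tr_stratum <- stats::setNames(base + extra, names(sizes))

  train_subjects <- character(0)
  with_seed(seed, {
    for (st in levels(strata)) {
      ids <- subj$subject_id[strata == st]
      if (length(ids) < 2L) {
        warning(sprintf("stratum '%s' has a single subject; assigned to training",
                        st))
        train_subjects <- c(train_subjects, ids)
        next
      }
      train_subjects <- c(train_subjects, sample(ids, n_tr_stratum[st]))
    }
  })
  val_subjects <- setdiff(subj$subject_id, train_subjects)
  new_split(metadata, scheme = "UPUS", seed = seed, balanced_on = balance,
            train_ids = metadata$sample_id[
              metadata$subject_id %in% train_subjects],
            val_ids = metadata$sample_id[
              metadata$subject_id %in% val_subjects])
}

#' Condition-crossed (OPUS) training/validation split
#'
#' "Overlapping participants and unique samples": for each subject, all
#' samples of one sleep-history condition go to training and all samples of
#' the other to validation, with the condition-to-side assignment
#' randomized subject-wise under the constraint that each side holds
#' sufficient- and insufficient-condition blocks in counts differing by at
#' most one. Subjects lacking one condition are excluded with a warning.
#'
#' @inheritParams split_upus
#' @return a \code{split_pair}.
#' @export
split_opus <- function(metadata, seed = 1L) {
  tab <- table(unique(metadata[, c("subject_id", "condition")]))
  complete <- rownames(tab)[rowSums(tab > 0) == 2L]
  incomplete <- setdiff(unique(metadata$subject_id), complete)
  if (length(incomplete))
    warning("subject(s) lacking one condition excluded: ",
            paste(incomplete, collapse = ", "))
  n <- length(complete)
  with_seed(seed, {
    shuffled <- sample(complete)
  })
  # first half contributes its sufficient-sleep block to training
  suff_to_train <- shuffled[seq_len(ceiling(n / 2))]
  md <- metadata[metadata$subject_id %in% complete, ]
  train_cond <- ifelse(md$subject_id %in% suff_to_train,
                       "sufficient", "insufficient")
  new_split(metadata, scheme = "OPUS", seed = seed, balanced_on = "condition",
            train_ids = md$sample_id[md$condition == train_cond],
            val_ids = md$sample_id[md$condition != train_cond])
}

new_split <- function(metadata, scheme, seed, balanced_on, train_ids,
                      val_ids) {
  stopifnot(length(intersect(train_ids, val_ids)) == 0L)
  structure(list(
    train_sample_ids = train_ids, validation_sample_ids = val_ids,
    train_subjects = unique(metadata$subject_id[
      metadata$sample_id %in% train_ids]),
    validation_subjects = unique(metadata$subject_id[
      metadata$sample_id %in% val_ids]),
    scheme = scheme, balanced_on = balanced_on, seed = seed),
    class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat(sprintf("%s split: %d train / %d validation samples (%d / %d subjects)\n",
              x$scheme, length(x$train_sample_ids),
              length(x$validation_sample_ids), length(x$train_subjects),
              length(x$validation_subjects)))
  invisible(x)
}

#' Write / read a split manifest (sample_id, side) as TSV
#' @param split a \code{split_pair}.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$train_sample_ids, split$validation_sample_ids),
    side = rep(c("train", "validation"),
               c(length(split$train_sample_ids),
                 length(split$validation_sample_ids))))
  write_tsv(df, path)
}

#' Assemble the labeled sample set for a sleep-debt variable
#'
#' Builds, from an expression matrix and its metadata (typically one side
#' of a split), the design matrix and target for one of the five sleep-debt
#' variables:
#' \describe{
#'   \item{time_awake}{regression on hours awake; \code{between} uses all
#'     samples, \code{within} uses baseline-corrected differential samples
#'     (#k - #1) labeled with the test sample's hours awake.}
#'   \item{gt24}{the same samples as time_awake with a two-class target,
#'     positive when hours awake exceeds 24.}
#'   \item{acute_loss}{\code{between}: samples #1 (negative) vs #9
#'     (positive) from both conditions; \code{within}: (#2 - #1) negative
#'     vs (#10 - #1) positive.}
#'   \item{chronic_insufficiency}{sample #1 of each condition (fallback #2
#'     when #1 is missing), class = sleep-history condition with
#'     insufficient positive; set \code{sample_index = 9} for the #9/#10
#'     variant.}
#'   \item{sleep_change}{per subject, the visit-1 minus visit-2 difference
#'     at sample #2 (fallback #3; \code{sample_index = 9} for the #9/#10
#'     variant); positive class = sleep decrease (sufficient-sleep visit
#'     first).}
#' }
#' Subjects whose blocks lack the required samples are excluded from the
#' affected variable only, with a warning.
#'
#' @param x an \code{expr_set} or features x samples matrix.
#' @param metadata sample metadata covering the samples of \code{x}.
#' @param variable one of \code{time_awake}, \code{gt24}, \code{acute_loss},
#'   \code{chronic_insufficiency}, \code{sleep_change}.
#' @param mode \code{"between"} (single samples) or \code{"within"}
#'   (baseline-corrected differences); ignored for
#'   \code{chronic_insufficiency} (between only) and \code{sleep_change}
#'   (within by construction).
#' @param sample_index variant selector for \code{chronic_insufficiency}
#'   (1 or 9) and \code{sleep_change} (2 or 9).
#' @param fallback allow the stated fallback sample index when the primary
#'   one is missing.
#' @return object of class \code{labeled_set}: \code{x} (units x features),
#'   \code{target} (numeric, or factor with levels negative/positive),
#'   \code{ids}, \code{subjects}, \code{variable}, \code{mode},
#'   \code{family}.
#' @export
assemble_variable <- function(x, metadata,
                              variable = c("time_awake", "gt24",
                                           "acute_loss",
                                           "chronic_insufficiency",
                                           "sleep_change"),
                              mode = c("between", "within"),
                              sample_index = NULL, fallback = TRUE) {
  variable <- match.arg(variable)
  mode <- match.arg(mode)
  es <- as_expr_set(x)
  md <- metadata[match(colnames(es$values), metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("metadata is missing sample(s) present in the matrix")

  if (variable %in% c("time_awake", "gt24")) {
    if (mode == "within") {
      bc <- baseline_correct(es, md, reference_index = 1,
                             reference_fallback = FALSE)
      es <- as_expr_set(bc$expression); md <- bc$metadata
    }
    target <- md$hours_awake
    out <- labeled_set(es, md, target, variable, mode, family = "linear")
    if (variable == "gt24") {
      out$target <- factor(ifelse(md$hours_awake > 24, "positive",
                                  "negative"),
                           levels = c("negative", "positive"))
      out$family <- "logistic"
      out$hours_awake <- md$hours_awake
    }
    return(out)
  }

  if (variable == "acute_loss") {
    if (mode == "between") {
      keep <- md$sample_index %in% c(1L, 9L)
      es <- expr_set(es$values[, keep, drop = FALSE],
                     es$flags[, keep, drop = FALSE])
      md <- md[keep, ]
      target <- factor(ifelse(md$sample_index == 9L, "positive", "negative"),
                       levels = c("negative", "positive"))
      return(labeled_set(es, md, target, variable, mode, "logistic"))
    }
    bc <- baseline_correct(es, md, reference_index = 1,
                           reference_fallback = FALSE)
    es <- as_expr_set(bc$expression); md <- bc$metadata
    keep <- md$sample_index %in% c(2L, 10L)
    es <- expr_set(es$values[, keep, drop = FALSE],
                   es$flags[, keep, drop = FALSE])
    md <- md[keep, ]
    target <- factor(ifelse(md$sample_index == 10L, "positive", "negative"),
                     levels = c("negative", "positive"))
    return(labeled_set(es, md, target, variable, mode, "logistic"))
  }

  if (variable == "chronic_insufficiency") {
    if (mode == "within")
      stop("chronic_insufficiency is a between-subject variable; ",
           "use `sleep_change` for the within-subject contrast")
    ref <- if (is.null(sample_index)) 1L else as.integer(sample_index)
    picked <- pick_block_samples(md, ref, fallback)
    es <- expr_set(es$values[, picked, drop = FALSE],
                   es$flags[, picked, drop = FALSE])
    md <- md[picked, ]
    target <- factor(ifelse(md$condition == "insufficient", "positive",
                            "negative"),
                     levels = c("negative", "positive"))
    return(labeled_set(es, md, target, variable, "between", "logistic"))
  }

  # sleep_change: per-subject visit-1 minus visit-2 differential sample
  ref <- if (is.null(sample_index)) 2L else as.integer(sample_index)
  subj <- unique(md$subject_id)
  cols <- list(); targ <- character(0); keep_subj <- character(0)
  dropped <- character(0)
  for (s in subj) {
    rows <- which(md$subject_id == s)
    v1 <- pick_one(md, rows[md$visit[rows] == 1L], ref, fallback)
    v2 <- pick_one(md, rows[md$visit[rows] == 2L], ref, fallback)
    if (is.na(v1) || is.na(v2)) { dropped <- c(dropped, s); next }
    cols[[s]] <- es$values[, v1] - es$values[, v2]
    # sleep decreased across visits when the sufficient week came first
    targ <- c(targ, if (md$condition[v1] == "sufficient") "positive"
                    else "negative")
    keep_subj <- c(keep_subj, s)
  }
  if (length(dropped))
    warning("subject(s) lacking usable visit samples excluded: ",
            paste(dropped, collapse = ", "))
  if (!length(cols)) stop("no eligible samples for sleep_change")
  vals <- do.call(cbind, cols)
  colnames(vals) <- keep_subj
  structure(list(x = t(vals),
                 target = factor(targ, levels = c("negative", "positive")),
                 ids = keep_subj, subjects = keep_subj,
                 variable = "sleep_change", mode = "within",
                 family = "logistic"),
            class = "labeled_set")
}

# one sample per (subject, condition) block at the given index, with
# fallback to index + 1
pick_block_samples <- function(md, ref, fallback) {
  blocks <- split(seq_len(nrow(md)), paste(md$subject_id, md$condition))
  picked <- integer(0); dropped <- character(0)
  for (bl in blocks) {
    i <- pick_one(md, bl, ref, fallback)
    if (is.na(i)) dropped <- c(dropped, paste0("(", md$subject_id[bl[1]],
                                               ", ", md$condition[bl[1]], ")"))
    else picked <- c(picked, i)
  }
  if (length(dropped))
    warning("block(s) lacking sample #", ref,
            if (fallback) paste0(" (and #", ref + 1, ")"),
            " excluded: ", paste(dropped, collapse = ", "))
  if (!length(picked)) stop("no eligible samples")
  picked
}

pick_one <- function(md, rows, ref, fallback) {
  i <- rows[md$sample_index[rows] == ref]
  if (!length(i) && fallback) i <- rows[md$sample_index[rows] == ref + 1]
  if (!length(i)) NA_integer_ else i[1]
}

labeled_set <- function(es, md, target, variable, mode, family) {
  structure(list(x = t(es$values), flags = t(es$flags), target = target,
                 ids = md$sample_id, subjects = md$subject_id,
                 variable = variable, mode = mode, family = family),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("labeled_set '%s' (%s, %s): %d units x %d features\n",
              x$variable, x$mode, x$family, nrow(x$x), ncol(x$x)))
  if (is.factor(x$target)) print(table(x$target))
  invisible(x)
}

#' Annotate metadata with each subject's visit-1 condition
#'
#' The condition a subject experienced at clinic visit 1 determines the
#' direction of their sleep change across visits; splits for the
#' sleep_change variable balance on it.
#'
#' @param metadata sample metadata with \code{visit} and \code{condition}.
#' @return metadata with an added \code{visit1_condition} column.
#' @export
add_visit1_condition <- function(metadata) {
  first <- unique(metadata[metadata$visit == 1,
                           c("subject_id", "condition")])
  metadata$visit1_condition <-
    first$condition[match(metadata$subject_id, first$subject_id)]
  metadata
}

#' Restrict an expression set and metadata to one side of a split
#'
#' @param x an \code{expr_set} or matrix.
#' @param metadata sample metadata.
#' @param sample_ids ids to keep (e.g. \code{split$train_sample_ids}).
#' @return list with \code{expression} and \code{metadata}.
#' @export
subset_samples <- function(x, metadata, sample_ids) {
  es <- as_expr_set(x)
  keep <- colnames(es$values) %in% sample_ids
  out <- expr_set(es$values[, keep, drop = FALSE],
                  es$flags[, keep, drop = FALSE])
  md <- metadata[match(colnames(out$values), metadata$sample_id), ]
  rownames(md) <- NULL
  list(expression = restore_type(out, x), metadata = md)
}
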