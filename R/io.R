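#' Read a log2 expression matrix (and optional flag matrix)
#'
#' Reads the TSV layout written by \code{\link{cohort_to_files}}: first
#' column \code{feature_id}, one column per sample. Tolerates CRLF endings
#' and quoted headers. Duplicate feature or sample ids and non-numeric
#' values are rejected with the offending id named.
#'
#' @param path expression TSV.
#' @param flags_path optional same-shape 0/1 flag TSV; defaults to an
#'   all-pass flag matrix.
#' @return list of class \code{expr_set}: \code{values} (features x samples
#'   numeric matrix), \code{flags} (same shape, 0/1).
#' @export
read_expression <- function(path, flags_path = NULL) {
  values <- read_matrix_tsv(path)
  if (!all(is.finite(values))) {
    bad <- rownames(values)[!stats::complete.cases(values)]
    stop("non-numeric or non-finite values in feature(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  flags <- if (is.null(flags_path)) {
    matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  } else {
    f <- read_matrix_tsv(flags_path)
    if (!all(f %in% c(0, 1))) stop("flags must be 0/1")
    if (!identical(dimnames(f), dimnames(values)))
      stop("flag matrix does not align with the expression matrix")
    f
  }
  expr_set(values, flags)
}

#' Construct an expression set
#'
#' @param values features x samples numeric matrix with dimnames.
#' @param flags optional same-shape 0/1 matrix.
#' @return an \code{expr_set}.
#' @export
expr_set <- function(values, flags = NULL) {
  values <- as.matrix(values)
  if (is.null(flags))
    flags <- matrix(0L, nrow(values), ncol(values),
                    dimnames = dimnames(values))
  if (!identical(dim(flags), dim(values)))
    stop("`flags` must have the same shape as `values`")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id(s): ",
         paste(utils::head(unique(rownames(values)[
           duplicated(rownames(values))]), 5), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(utils::head(unique(colnames(values)[
           duplicated(colnames(values))]), 5), collapse = ", "))
  structure(list(values = values, flags = flags), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d features x %d samples (%.2f%% flagged)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$flags)))
  invisible(x)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(as.data.frame(m), is.numeric, logical(1))]
    stop("non-numeric column(s) in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read per-sample design metadata
#'
#' Columns: sample_id, subject_id, sex, condition (sufficient/insufficient),
#' visit (1/2), sample_index (1..10), hours_awake, clock_time. Validates
#' uniqueness of (subject, condition, sample_index) and the hours-awake
#' range of the constant-routine protocol (7 to 35 hr).
#'
#' @param path samples TSV.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "subject_id", "condition", "sample_index",
            "hours_awake")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id(s): ",
         paste(utils::head(unique(md$sample_id[duplicated(md$sample_id)]), 5),
               collapse = ", "))
  key <- paste(md$subject_id, md$condition, md$sample_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, condition, sample_index): ",
         utils::head(key[duplicated(key)], 1))
  if (!all(md$condition %in% c("sufficient", "insufficient")))
    stop("`condition` must be 'sufficient' or 'insufficient'")
  if (any(!is.finite(md$hours_awake)) ||
      any(md$hours_awake < 7 | md$hours_awake > 35))
    stop("`hours_awake` must lie within [7, 35]")
  md
}

#' Read a full cohort directory
#'
#' Reads expression, flags, samples (and, when present, truth) from the
#' layout of \code{\link{cohort_to_files}}, and checks that the expression
#' and metadata sample sets match exactly.
#'
#' @param dir cohort directory.
#' @return list with \code{expression} (\code{expr_set}), \code{metadata},
#'   and \code{truth} (or NULL).
#' @export
read_cohort <- function(dir) {
  es <- read_expression(file.path(dir, "expression.tsv"),
                        if (file.exists(file.path(dir, "flags.tsv")))
                          file.path(dir, "flags.tsv"))
  md <- read_metadata(file.path(dir, "samples.tsv"))
  only_x <- setdiff(colnames(es$values), md$sample_id)
  only_m <- setdiff(md$sample_id, colnames(es$values))
  if (length(only_x) || length(only_m))
    stop("sample sets of matrix and metadata differ; ",
         if (length(only_x)) paste0("matrix-only: ",
           paste(utils::head(only_x, 5), collapse = ", "), " "),
         if (length(only_m)) paste0("metadata-only: ",
           paste(utils::head(only_m, 5), collapse = ", ")))
  md <- md[match(colnames(es$values), md$sample_id), ]
  rownames(md) <- NULL
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  list(expression = es, metadata = md, truth = truth)
}

#' Percentile normalization
#'
#' Shifts each sample so that its p-th percentile (linear-interpolation
#' convention, R quantile type 7) is zero: on the log2 scale this is the
#' additive analogue of 75th-percentile scaling and is idempotent.
#'
#' @param x an \code{expr_set} or a features x samples matrix.
#' @param p percentile in (0, 100), default 75.
#' @return same type as \code{x}, normalized.
#' @export
percentile_normalize <- function(x, p = 75) {
  es <- as_expr_set(x)
  if (nrow(es$values) < 2L)
    stop("percentile normalization needs >= 2 values per sample")
  q <- apply(es$values, 2, stats::quantile, probs = p / 100, names = FALSE,
             type = 7)
  es$values <- sweep(es$values, 2, q, "-")
  restore_type(es, x)
}

as_expr_set <- function(x) {
  if (inherits(x, "expr_set")) x else expr_set(x)
}
restore_type <- function(es, orig) {
  if (inherits(orig, "expr_set")) es else es$values
}

#' Average technically replicated features
#'
#' Collapses feature rows that map to the same replicate group to their
#' arithmetic mean; a group is flagged in a sample if any member is flagged.
#'
#' @param x an \code{expr_set} or matrix.
#' @param replicate_map named character vector (names = feature ids,
#'   values = group ids); every feature of \code{x} must be mapped.
#' @return same type as \code{x}, one row per group.
#' @export
average_replicates <- function(x, replicate_map) {
  es <- as_expr_set(x)
  ids <- rownames(es$values)
  miss <- setdiff(ids, names(replicate_map))
  if (length(miss))
    stop("unmapped feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  g <- as.character(replicate_map[ids])
  if (any(is.na(g) | !nzchar(g))) stop("replicate groups must be non-empty")
  values <- rowsum(es$values, g) / as.vector(table(g)[sort(unique(g))])
  flags <- (rowsum(es$flags, g) > 0) * 1L
  es$values <- values[sort(unique(g)), , drop = FALSE]
  es$flags <- flags[sort(unique(g)), , drop = FALSE]
  restore_type(es, x)
}

#' Remove features flagged in more than a fraction of training samples
#'
#' A feature is removed when it is quality-flagged in strictly more than
#' \code{threshold} of the training samples (the strict more-than-10%
#' rule). Removal is decided on the training set only and applied
#' identically to every supplied matrix; validation flags never influence
#' the decision.
#'
#' @param train training \code{expr_set}.
#' @param apply_to list of further \code{expr_set}s sharing the feature set.
#' @param threshold flagged-fraction cutoff (strict inequality).
#' @return list with \code{train}, \code{apply_to}, and \code{removed}
#'   (character vector of dropped features).
#' @export
filter_flagged <- function(train, apply_to = list(), threshold = 0.10) {
  train <- as_expr_set(train)
  apply_to <- lapply(apply_to, as_expr_set)
  for (m in apply_to) {
    if (!identical(rownames(m$values), rownames(train$values)))
      stop("feature sets differ between training and apply_to matrices")
  }
  frac <- rowMeans(train$flags)
  keep <- frac <= threshold
  list(train = expr_set(train$values[keep, , drop = FALSE],
                        train$flags[keep, , drop = FALSE]),
       apply_to = lapply(apply_to, function(m)
         expr_set(m$values[keep, , drop = FALSE],
                  m$flags[keep, , drop = FALSE])),
       removed = rownames(train$values)[!keep])
}

#' Baseline-correct samples within (subject, condition) blocks
#'
#' Transforms each non-reference sample to test minus reference within its
#' (subject, condition) block -- the within-subject differencing that
#' removes trait-like subject signatures. Reference samples are dropped
#' from the output. Blocks lacking the reference sample are excluded with
#' a warning naming (subject, condition); with \code{reference_fallback}
#' the next sample index stands in as reference.
#'
#' @param x an \code{expr_set} or matrix.
#' @param metadata sample metadata aligned by sample_id.
#' @param reference_index sample index of the baseline (default 1).
#' @param reference_fallback use \code{reference_index + 1} as reference
#'   when the reference sample is missing from a block.
#' @return list with \code{expression} (same type as \code{x}) and
#'   \code{metadata} for the retained (differenced) samples.
#' @export
baseline_correct <- function(x, metadata, reference_index = 1,
                             reference_fallback = FALSE) {
  es <- as_expr_set(x)
  md <- metadata[match(colnames(es$values), metadata$sample_id), ]
  if (any(is.na(md$sample_id)))
    stop("metadata is missing sample(s) present in the matrix")
  blocks <- split(seq_len(nrow(md)), paste(md$subject_id, md$condition))
  keep_cols <- integer(0)
  dropped <- character(0)
  out_vals <- NULL
  for (bl in blocks) {
    ref <- bl[md$sample_index[bl] == reference_index]
    if (!length(ref) && reference_fallback)
      ref <- bl[md$sample_index[bl] == reference_index + 1]
    if (!length(ref)) {
      dropped <- c(dropped, paste0("(", md$subject_id[bl[1]], ", ",
                                   md$condition[bl[1]], ")"))
      next
    }
    tests <- setdiff(bl, ref)
    if (!length(tests)) next
    d <- es$values[, tests, drop = FALSE] - es$values[, ref]
    out_vals <- if (is.null(out_vals)) d else cbind(out_vals, d)
    keep_cols <- c(keep_cols, tests)
  }
  if (length(dropped))
    warning("blocks without reference sample excluded: ",
            paste(dropped, collapse = ", "))
  if (is.null(out_vals)) stop("no blocks with a reference sample")
  out <- expr_set(out_vals, es$flags[, keep_cols, drop = FALSE])
  list(expression = restore_type(out, x),
       metadata = {
         m <- md[keep_cols, ]
         rownames(m) <- NULL
         m
       })
}
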