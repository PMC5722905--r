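#' Multi-series time-course expression matrix
#'
#' Bundles a genes x samples matrix of non-negative expression values with a
#' per-sample design (series identifier, time, optional cyclic flag). This is
#' the input container for the RANGES/ExRANGES transform: a "series" is one
#' self-contained time course (a tissue, a subject, a biological replicate
#' run) and slopes are only ever taken between consecutive samples of the
#' same series.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All entries must be finite and
#'   non-negative; missing values are not handled here.
#' @param design data.frame with columns `sample_id`, `series_id`, `time`
#'   (numeric) and optionally `cyclic` (logical, constant within a series;
#'   default `FALSE`). Every sample in `values` must appear exactly once.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (matrix, columns reordered by series then time) and `design`
#'   (data.frame aligned to the columns).
#' @examples
#' em <- expression_matrix(
#'   matrix(1:8, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
#'   data.frame(sample_id = paste0("s", 1:4),
#'              series_id = c("a", "a", "b", "b"), time = c(0, 2, 0, 2))
#' )
#' dim(em$values)
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite with no missing entries")
  if (any(values < 0))
    stop("expression values must be non-negative")

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- c("sample_id", "series_id", "time")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  design$series_id <- as.character(design$series_id)
  if (!is.numeric(design$time) || !all(is.finite(design$time)))
    stop("design `time` must be finite numeric")
  if (is.null(design$cyclic)) design$cyclic <- FALSE
  if (!is.logical(design$cyclic) || anyNA(design$cyclic))
    stop("design `cyclic` must be TRUE/FALSE")
  if (anyDuplicated(design$sample_id))
    stop("design has duplicate sample_id entries: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))

  only_design <- setdiff(design$sample_id, colnames(values))
  only_matrix <- setdiff(colnames(values), design$sample_id)
  if (length(only_design) || length(only_matrix))
    stop("matrix/design sample mismatch; ",
         if (length(only_design))
           paste0("in design only: ", paste(only_design, collapse = ", "), "; ") else "",
         if (length(only_matrix))
           paste0("in matrix only: ", paste(only_matrix, collapse = ", ")) else "")

  for (sid in unique(design$series_id)) {
    tt <- design$time[design$series_id == sid]
    if (anyDuplicated(tt))
      stop("series '", sid, "' has duplicate time values")
    cy <- design$cyclic[design$series_id == sid]
    if (length(unique(cy)) > 1L)
      stop("series '", sid, "' mixes cyclic flags")
  }

  ord <- order(design$series_id, design$time)
  design <- design[ord, req <- c("sample_id", "series_id", "time", "cyclic"),
                   drop = FALSE]
  rownames(design) <- NULL
  values <- values[, design$sample_id, drop = FALSE]

  structure(list(values = values, design = design), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  ns <- table(x$design$series_id)
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples in", length(ns), "series\n")
  cat("  samples/series:", paste0(names(ns), "=", as.integer(ns), collapse = ", "),
      "\n")
  cat("  cyclic series:", sum(tapply(x$design$cyclic, x$design$series_id, `[`, 1L)),
      "of", length(ns), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

#' Configuration for the RANGES/ExRANGES transform
#'
#' @param bootstrap logical; if `TRUE` (the default) the per-gene slope
#'   background is a bootstrap resample (`bootstrap_reps` draws with
#'   replacement) of the pooled slopes, as in the original method; if `FALSE`
#'   ("direct" mode) the pooled slopes themselves serve as the reference
#'   multiset, which makes p-values exactly reproducible by tail counting.
#' @param bootstrap_reps positive integer, bootstrap sample size (default
#'   10000).
#' @param seed integer seed governing the bootstrap; the transform is
#'   deterministic given `(expr, cfg)`.
#' @param tail `"smaller"` (default) scores a slope by its smaller empirical
#'   tail, so extreme changes of either sign are significant; `"literal"`
#'   keeps the larger-tail form (p >= 0.5 always, capping |R| at ~0.301) and
#'   exists only for comparison with the method as originally printed.
#' @param wrap_interval optional positive number: the time interval assigned
#'   to the wrap step (last sample back to first) of a cyclic series. The
#'   default `NULL` uses each series' median within-series time gap, which
#'   for an evenly sampled series equals every other step's interval.
#' @return a list of class `TransformConfig`.
#' @export
transform_config <- function(bootstrap = TRUE, bootstrap_reps = 10000L,
                             seed = 1L, tail = c("smaller", "literal"),
                             wrap_interval = NULL) {
  tail <- match.arg(tail)
  bootstrap_reps <- as.integer(bootstrap_reps)
  if (is.na(bootstrap_reps) || bootstrap_reps < 1L)
    stop("bootstrap_reps must be a positive integer")
  if (!is.null(wrap_interval) &&
      (!is.numeric(wrap_interval) || wrap_interval <= 0))
    stop("wrap_interval must be a positive number")
  structure(list(bootstrap = isTRUE(bootstrap),
                 bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed), tail = tail,
                 wrap_interval = wrap_interval),
            class = "TransformConfig")
}
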