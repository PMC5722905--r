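#' Configuration for tree-ensemble edge scoring
#'
#' @param n_trees number of regression trees per target (default 2000; a
#'   reduced count such as 100 is appropriate for large target sets, at some
#'   cost in score stability).
#' @param importance `"permutation"` (default): mean increase in out-of-bag
#'   MSE when one regulator's values are permuted — the mean decrease in
#'   accuracy. `"variance"`: total variance reduction at splits on that
#'   regulator (the canonical GENIE3 importance), kept for cross-checking.
#' @param mtry number of regulators sampled at each split; default
#'   `sqrt(#regulators)` rounded down (at least 1).
#' @param standardize centre and scale each feature row to unit variance
#'   before fitting (the GENIE3 convention); constant rows are left centred.
#' @param normalize if `TRUE`, divide each target's importances by their
#'   positive sum before pooling into a global ranking. Off by default:
#'   with permutation importance on unit-variance target profiles, raw
#'   importances are already on a common scale (fraction of target variance
#'   lost when the regulator is permuted), whereas sum-normalization
#'   inflates the near-zero noise importances of unpredictable targets to
#'   the same total edge mass as well-predicted ones and corrupts the
#'   pooled ranking.
#' @param seed integer; per-target fits draw reproducible sub-seeds from it.
#' @param n_jobs number of worker processes across targets. Scores are
#'   identical for any `n_jobs`: each target's fit is single-threaded and
#'   seeded by target index, so parallelism never changes the result.
#' @return a list of class `InferenceConfig`.
#' @export
inference_config <- function(n_trees = 2000L,
                             importance = c("permutation", "variance"),
                             mtry = NULL, standardize = TRUE,
                             normalize = FALSE, seed = 1L, n_jobs = 1L) {
  importance <- match.arg(importance)
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be a positive integer")
  structure(list(n_trees = n_trees, importance = importance, mtry = mtry,
                 standardize = isTRUE(standardize),
                 normalize = isTRUE(normalize),
                 seed = as.integer(seed), n_jobs = as.integer(n_jobs)),
            class = "InferenceConfig")
}

#' Importance of each regulator for one target
#'
#' Fits an ensemble of regression trees of the target's feature profile on
#' the candidate regulators' profiles and returns one importance per
#' regulator: by default the mean increase in out-of-bag prediction error
#' when that regulator's values are randomly permuted. A constant target
#' carries no signal and returns all-zero importances.
#'
#' @param target_profile numeric vector (one observation per column of the
#'   feature matrix).
#' @param regulator_profiles numeric matrix, regulators x observations, with
#'   regulator rownames. The target itself must not be among the rows.
#' @param cfg an [inference_config()].
#' @param seed optional integer overriding `cfg$seed` for this single fit.
#' @return named numeric vector of importances, one per regulator.
#' @export
score_target <- function(target_profile, regulator_profiles,
                         cfg = inference_config(), seed = NULL) {
  if (!is.matrix(regulator_profiles) || is.null(rownames(regulator_profiles)))
    stop("regulator_profiles must be a matrix with regulator rownames")
  p <- nrow(regulator_profiles)
  n <- ncol(regulator_profiles)
  if (p < 2L) stop("need at least 2 candidate regulators")
  if (length(target_profile) != n)
    stop("target profile length (", length(target_profile),
         ") does not match observation count (", n, ")")
  if (n < 10L) stop("need at least 10 observations, got ", n)
  regs <- rownames(regulator_profiles)
  if (stats::sd(target_profile) == 0)
    return(stats::setNames(numeric(p), regs))
  if (is.null(seed)) seed <- cfg$seed
  mtry <- cfg$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  df <- data.frame(..y = as.numeric(target_profile),
                   t(regulator_profiles), check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = cfg$n_trees, mtry = mtry,
    importance = if (cfg$importance == "permutation") "permutation" else "impurity",
    seed = seed, num.threads = 1L, respect.unordered.factors = FALSE)
  imp <- fit$variable.importance[regs]
  names(imp) <- regs
  imp[!is.finite(imp)] <- 0
  imp
}

#' Score all regulator-to-target edges from a feature matrix
#'
#' Runs one [score_target()] regression per target and assembles the
#' importances into a regulators x targets score matrix. The engine is
#' feature-agnostic: columns are treated as exchangeable observations, so
#' raw expression samples, RANGES steps or ExRANGES steps all work, with
#' differing column counts. Self-edges (a regulator predicting itself) are
#' never fitted and are `NA` in the matrix; regulators may appear among the
#' targets to recover regulator-regulator edges.
#'
#' @param features numeric genes x observations matrix with gene rownames,
#'   or a `RangesMatrix`/`ExRangesMatrix` (their `values` are used).
#' @param regulators character vector of candidate regulator gene ids
#'   (must all be rows of `features`).
#' @param targets character vector of target gene ids; default all genes.
#' @param cfg an [inference_config()].
#' @return a list of class `EdgeScoreMatrix`: `scores` (regulators x
#'   targets, `NA` on self-edges), `config`, `feature_type`.
#' @export
infer_network <- function(features, regulators, targets = NULL,
                          cfg = inference_config()) {
  feature_type <- class(features)[1L]
  if (inherits(features, c("RangesMatrix", "ExRangesMatrix")))
    features <- features$values
  if (inherits(features, "ExpressionMatrix")) features <- features$values
  if (!is.matrix(features) || is.null(rownames(features)))
    stop("features must be a matrix with gene rownames")
  genes <- rownames(features)
  regulators <- as.character(regulators)
  if (length(regulators) == 0L) stop("empty regulator set")
  bad <- setdiff(regulators, genes)
  if (length(bad))
    stop("regulators absent from feature matrix: ", paste(bad, collapse = ", "))
  if (is.null(targets)) targets <- genes
  bad <- setdiff(targets, genes)
  if (length(bad))
    stop("targets absent from feature matrix: ", paste(bad, collapse = ", "))

  # canonical observation order: columns are exchangeable observations, so
  # sort them lexicographically by feature values — scores are then
  # invariant to the input's column order (tree bootstraps are positional)
  X <- features
  X <- X[, do.call(order, as.data.frame(t(X))), drop = FALSE]
  if (cfg$standardize) {
    mu <- rowMeans(X)
    sd <- apply(X, 1L, stats::sd)
    sd[sd == 0] <- 1
    X <- (X - mu) / sd
  }

  one_target <- function(j) {
    tg <- targets[j]
    reg_j <- setdiff(regulators, tg)
    if (length(reg_j) < 2L)
      stop("target '", tg, "' leaves fewer than 2 candidate regulators")
    imp <- score_target(X[tg, ], X[reg_j, , drop = FALSE], cfg,
                        seed = (cfg$seed + j) %% .Machine$integer.max)
    if (cfg$normalize) {
      pos <- pmax(imp, 0)
      if (sum(pos) > 0) imp <- pos / sum(pos) else imp <- pos
    }
    out <- stats::setNames(rep(NA_real_, length(regulators)), regulators)
    out[reg_j] <- imp
    out
  }

  cols <- if (cfg$n_jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(targets), one_target, mc.cores = cfg$n_jobs)
  } else {
    lapply(seq_along(targets), one_target)
  }
  scores <- do.call(cbind, cols)
  dimnames(scores) <- list(regulators, targets)
  structure(list(scores = scores, config = cfg, feature_type = feature_type),
            class = "EdgeScoreMatrix")
}

#' Rank edges by score
#'
#' Flattens an edge score matrix into an ordered edge list, highest score
#' first, with deterministic lexical tie-breaking on (regulator, target) so
#' rankings — and everything downstream, ROC and recall included — are
#' bit-reproducible. Self-edges (`NA` scores) are excluded.
#'
#' @param scores an `EdgeScoreMatrix` from [infer_network()], or a bare
#'   regulators x targets matrix.
#' @param top_fraction keep the top `ceiling(top_fraction * n_edges)` edges,
#'   `top_fraction` in (0, 1].
#' @param top_k alternatively keep the top `top_k` edges.
#' @return data.frame with columns `regulator`, `target`, `score`, ordered.
#' @export
rank_edges <- function(scores, top_fraction = NULL, top_k = NULL) {
  m <- if (inherits(scores, "EdgeScoreMatrix")) scores$scores else scores
  if (!is.matrix(m) || length(m) == 0L) stop("empty edge score matrix")
  if (!all(is.finite(m) | is.na(m))) stop("edge scores must be finite")
  df <- data.frame(
    regulator = rep(rownames(m), times = ncol(m)),
    target = rep(colnames(m), each = nrow(m)),
    score = as.vector(m), stringsAsFactors = FALSE)
  df <- df[!is.na(df$score), , drop = FALSE]
  df <- df[order(-df$score, df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(top_fraction)) {
    if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
      stop("top_fraction must be in (0, 1]")
    df <- df[seq_len(ceiling(top_fraction * nrow(df))), , drop = FALSE]
  } else if (!is.null(top_k)) {
    df <- df[seq_len(min(as.integer(top_k), nrow(df))), , drop = FALSE]
  }
  df
}

#' @export
print.EdgeScoreMatrix <- function(x, ...) {
  cat("EdgeScoreMatrix:", nrow(x$scores), "regulators x", ncol(x$scores),
      "targets (", x$config$importance, "importance,", x$config$n_trees,
      "trees, features:", x$feature_type, ")\n")
  invisible(x)
}
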