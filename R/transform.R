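#' Consecutive-step slopes for every gene
#'
#' Computes, for every gene, the expression rate of change over every
#' consecutive pair of time points within each series. For a non-cyclic
#' series of N samples there are N - 1 steps; a cyclic series gains a wrap
#' step from its last sample back to its first, taken as a forward step of
#' length `wrap_interval` (by default the series' median within-series time
#' gap). Steps never pair samples from different series. Each step is
#' attached to its from-sample, i.e. the slope over [t, t+1] belongs to
#' time t.
#'
#' @param expr an [expression_matrix()].
#' @param cfg a [transform_config()]; only `wrap_interval` is used here.
#' @return a list of class `SlopeSet`: `slopes` (genes x steps matrix),
#'   `signs` (same shape, in {-1, 0, 1}), and `steps` (data.frame with
#'   `series_id`, `from_sample`, `from_time`, `to_time`, `dt`, `wrap`).
#'   Step columns are labelled `series_id:from_time`.
#' @export
compute_slopes <- function(expr, cfg = transform_config()) {
  stopifnot(is_expression_matrix(expr))
  d <- expr$design
  steps <- list()
  for (sid in unique(d$series_id)) {
    idx <- which(d$series_id == sid)          # already time-sorted
    n <- length(idx)
    if (n < 2L)
      stop("series '", sid, "' has fewer than 2 samples; cannot form slopes")
    tt <- d$time[idx]
    cyc <- d$cyclic[idx[1L]]
    from <- idx[seq_len(n - 1L)]
    to <- idx[seq_len(n - 1L) + 1L]
    dt <- tt[-1L] - tt[-n]
    wrap <- rep(FALSE, n - 1L)
    if (cyc) {
      dw <- cfg$wrap_interval
      if (is.null(dw)) dw <- stats::median(dt)
      from <- c(from, idx[n]); to <- c(to, idx[1L])
      dt <- c(dt, dw); wrap <- c(wrap, TRUE)
    }
    steps[[sid]] <- data.frame(
      series_id = sid,
      from_sample = d$sample_id[from], to_sample = d$sample_id[to],
      from_time = d$time[from], to_time = d$time[to],
      dt = dt, wrap = wrap, stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  x_from <- expr$values[, steps$from_sample, drop = FALSE]
  x_to <- expr$values[, steps$to_sample, drop = FALSE]
  slopes <- sweep(x_to - x_from, 2L, steps$dt, `/`)
  colnames(slopes) <- step_labels(steps)
  structure(list(slopes = slopes, signs = sign(slopes), steps = steps),
            class = "SlopeSet")
}

step_labels <- function(steps) {
  paste0(steps$series_id, ":", format(steps$from_time, trim = TRUE,
                                      scientific = FALSE))
}

#' Per-gene slope background
#'
#' Pools one gene's step slopes across all series into the reference
#' multiset against which each of its slopes is scored. With
#' `cfg$bootstrap = TRUE` the reference is a seeded resample of
#' `cfg$bootstrap_reps` draws with replacement (the method's original form);
#' in direct mode the pooled slopes are used as-is.
#'
#' @param slopes numeric vector of one gene's pooled slopes (a row of
#'   `SlopeSet$slopes`).
#' @param cfg a [transform_config()].
#' @param stream integer offset mixed into the seed so that each gene draws
#'   an independent, reproducible bootstrap substream.
#' @return a list of class `BackgroundDistribution` with `pooled` (sorted)
#'   and `reference` (sorted multiset actually used for tail counting).
#' @export
build_background <- function(slopes, cfg = transform_config(), stream = 0L) {
  slopes <- as.numeric(slopes)
  if (length(slopes) == 0L) stop("empty slope set: no background to build")
  if (length(slopes) < 2L) stop("need at least 2 pooled slopes for a background")
  reference <- slopes
  if (cfg$bootstrap) {
    # private RNG stream: per-gene resample independent of the caller's RNG
    rs <- local({
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
              else suppressWarnings(rm(".Random.seed", envir = globalenv())))
      set.seed((cfg$seed + 7919L * (stream %% 262144L)) %% .Machine$integer.max)
      sample(slopes, cfg$bootstrap_reps, replace = TRUE)
    })
    reference <- rs
  }
  structure(list(pooled = sort(slopes), reference = sort(reference)),
            class = "BackgroundDistribution")
}

#' Empirical tail p-value of a slope against a background
#'
#' Scores how extreme a slope is within a reference multiset of slopes. The
#' default form takes the smaller of the two empirical tails with add-one
#' smoothing, `p = (min(#{b <= s}, #{b >= s}) + 1) / (B + 1)`, so extreme
#' changes of either sign get small p and p is never 0 (the sign of the
#' change travels separately into the RANGES value). `tail = "literal"`
#' instead keeps the larger tail (`max` in place of `min`), the form the
#' method was originally printed with; it bounds p below by 0.5 and exists
#' for comparison only.
#'
#' @param slope numeric vector of slopes to score.
#' @param background a [build_background()] result (or any numeric vector,
#'   taken as the reference multiset).
#' @param tail `"smaller"` or `"literal"`.
#' @return numeric vector of p-values in (0, 1].
#' @export
tail_pvalue <- function(slope, background, tail = c("smaller", "literal")) {
  tail <- match.arg(tail)
  ref <- if (inherits(background, "BackgroundDistribution"))
    background$reference else sort(as.numeric(background))
  if (length(ref) == 0L) stop("empty background")
  B <- length(ref)
  n_le <- findInterval(slope, ref)                       # #{b <= s}
  n_lt <- findInterval(slope, ref, left.open = TRUE)     # #{b <  s}
  n_ge <- B - n_lt
  pick <- if (tail == "smaller") pmin(n_le, n_ge) else pmax(n_le, n_ge)
  (pick + 1) / (B + 1)
}

#' RANGES: signed rate-change significance matrix
#'
#' The full transform: per-gene consecutive-step slopes, a pooled
#' (optionally bootstrapped) per-gene background, an empirical tail p-value
#' for every step, and finally `R = -log10(p) * sign(slope)`. Flat steps
#' (slope exactly 0) get R = 0. The result is a genes x steps matrix on a
#' dimensionless -log10 scale whose sign records the direction of change;
#' it is invariant under per-gene positive rescaling of expression and
#' under global positive rescaling of time.
#'
#' @param expr an [expression_matrix()].
#' @param cfg a [transform_config()].
#' @return a list of class `RangesMatrix`: `values` (genes x steps), `steps`
#'   (step metadata as in [compute_slopes()]), `config` (the `cfg` used).
#' @export
ranges <- function(expr, cfg = transform_config()) {
  ss <- compute_slopes(expr, cfg)
  R <- ss$slopes
  for (i in seq_len(nrow(R))) {
    bg <- build_background(ss$slopes[i, ], cfg, stream = i - 1L)
    p <- tail_pvalue(ss$slopes[i, ], bg, tail = cfg$tail)
    R[i, ] <- -log10(p) * ss$signs[i, ]
  }
  structure(list(values = R, steps = ss$steps, config = cfg),
            class = "RangesMatrix")
}

#' ExRANGES: expression level times rate-change significance
#'
#' Multiplies each RANGES value by the expression level at the step's
#' from-sample: `E = R * X[, from_sample]`. The expression level preceding
#' a significant change is thereby emphasized; samples that start no step
#' (the last sample of a non-cyclic series) contribute no column.
#'
#' @param expr the [expression_matrix()] the RANGES matrix was computed
#'   from.
#' @param R a [ranges()] result.
#' @return a list of class `ExRangesMatrix` with the same shape and step
#'   metadata as `R`.
#' @export
exranges <- function(expr, R) {
  stopifnot(is_expression_matrix(expr), inherits(R, "RangesMatrix"))
  if (!all(R$steps$from_sample %in% colnames(expr$values)))
    stop("step metadata names samples absent from the expression matrix")
  if (!identical(rownames(R$values), rownames(expr$values)))
    stop("gene sets of expression matrix and RANGES matrix differ")
  E <- R$values * expr$values[, R$steps$from_sample, drop = FALSE]
  colnames(E) <- colnames(R$values)
  structure(list(values = E, steps = R$steps, config = R$config),
            class = "ExRangesMatrix")
}

#' @export
print.RangesMatrix <- function(x, ...) {
  cat("RangesMatrix:", nrow(x$values), "genes x", ncol(x$values), "steps",
      sprintf("(%s tail, %s background)\n", x$config$tail,
              if (x$config$bootstrap)
                paste0("bootstrap B=", x$config$bootstrap_reps) else "direct"))
  invisible(x)
}

#' @export
print.ExRangesMatrix <- function(x, ...) {
  cat("ExRangesMatrix:", nrow(x$values), "genes x", ncol(x$values), "steps\n")
  invisible(x)
}
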