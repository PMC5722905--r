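#' Gold-standard target set for one regulator
#'
#' Experimentally supported positive targets (e.g. derived from ChIP-Seq or
#' DAP-Seq) of one regulator, within the universe of genes the inference run
#' actually scored. Predictions are labelled positive/negative against this
#' set for ROC and precision-recall evaluation.
#'
#' @param regulator regulator gene id.
#' @param positives character vector of positive target ids.
#' @param universe character vector of all evaluated target ids; must
#'   contain every positive.
#' @return a list of class `GoldStandard`.
#' @export
gold_standard <- function(regulator, positives, universe) {
  positives <- unique(as.character(positives))
  universe <- unique(as.character(universe))
  bad <- setdiff(positives, universe)
  if (length(bad))
    stop("positives outside universe for '", regulator, "': ",
         paste(utils::head(bad, 5L), collapse = ", "))
  structure(list(regulator = as.character(regulator),
                 positives = positives, universe = universe),
            class = "GoldStandard")
}

#' ROC curve and AUC of predicted target scores
#'
#' Area under the receiver-operating-characteristic curve of the per-target
#' prediction scores against a gold standard, computed as the Mann-Whitney
#' statistic: the probability that a random positive outscores a random
#' negative, ties counting one half (so uninformative all-equal scores give
#' exactly 0.5). Curve points are evaluated at every distinct threshold.
#'
#' @param scores named numeric vector of prediction scores; names must
#'   cover the gold standard's universe.
#' @param gold a [gold_standard()].
#' @return a list of class `RocResult`: `auc`, `curve` (data.frame with
#'   `threshold`, `fpr`, `tpr`), `n_positive`, `n_universe`.
#' @export
roc_auc <- function(scores, gold) {
  s <- aligned_scores(scores, gold)
  lab <- names(s) %in% gold$positives
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L)
    stop("regulator '", gold$regulator, "': need at least one positive and ",
         "one negative target (", np, " positives of ", length(s), ")")
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(s), decreasing = TRUE)
  o <- order(-s)
  cs <- cumsum(lab[o])
  last <- cumsum(tabulate(match(s[o], thr), nbins = length(thr)))
  tp <- cs[last]
  fp <- last - tp
  curve <- data.frame(threshold = thr, fpr = fp / nn, tpr = tp / np)
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), curve)
  structure(list(auc = auc, curve = curve, n_positive = np,
                 n_universe = length(s)), class = "RocResult")
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct score threshold, with average
#' precision by step-wise integration (sum over thresholds of precision
#' times the recall increment). All-equal scores yield the positive rate.
#'
#' @inheritParams roc_auc
#' @return a list of class `PrResult`: `average_precision`, `curve`
#'   (data.frame with `threshold`, `recall`, `precision`), `n_positive`.
#' @export
pr_curve <- function(scores, gold) {
  s <- aligned_scores(scores, gold)
  lab <- names(s) %in% gold$positives
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L)
    stop("regulator '", gold$regulator, "': need at least one positive and ",
         "one negative target")
  thr <- sort(unique(s), decreasing = TRUE)
  o <- order(-s)
  cum_tp <- cumsum(lab[o])
  last <- cumsum(tabulate(match(s[o], thr), nbins = length(thr)))
  tp <- cum_tp[last]
  precision <- tp / last
  recall <- tp / np
  ap <- sum(precision * diff(c(0, recall)))
  structure(list(average_precision = ap,
                 curve = data.frame(threshold = thr, recall = recall,
                                    precision = precision),
                 n_positive = np), class = "PrResult")
}

aligned_scores <- function(scores, gold) {
  if (!inherits(gold, "GoldStandard")) stop("gold must be a GoldStandard")
  if (is.null(names(scores))) stop("scores must be named by target id")
  miss <- setdiff(gold$universe, names(scores))
  if (length(miss))
    stop("scores missing for ", length(miss), " universe target(s), e.g. ",
         paste(utils::head(miss, 3L), collapse = ", "))
  s <- scores[gold$universe]
  if (!all(is.finite(s))) stop("non-finite prediction scores")
  s
}

#' Coefficient of variation per gene
#'
#' `CV = sd / mean` of each gene's expression across all samples (sd with
#' the n-1 denominator). Scale-free, so genes of very different absolute
#' abundance are comparable; used to profile how variable a method's
#' top-ranked targets are. Genes with zero mean cannot be scored and are
#' dropped with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param gene_set character vector of gene ids; default all genes.
#' @return named numeric vector of CVs.
#' @export
coefficient_of_variation <- function(expr, gene_set = NULL) {
  stopifnot(is_expression_matrix(expr))
  if (is.null(gene_set)) gene_set <- rownames(expr$values)
  bad <- setdiff(gene_set, rownames(expr$values))
  if (length(bad)) stop("unknown gene(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  v <- expr$values[gene_set, , drop = FALSE]
  mu <- rowMeans(v)
  zero <- mu == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero mean excluded from CV: ",
            paste(utils::head(gene_set[zero], 5L), collapse = ", "))
    v <- v[!zero, , drop = FALSE]; mu <- mu[!zero]
  }
  apply(v, 1L, stats::sd) / mu
}

#' Within- and between-series standard deviation per gene
#'
#' Decomposes each gene's variability into the mean across series of its
#' within-series SD, and the SD of its per-series means (all SDs with the
#' n-1 denominator). Large between/within ratios indicate series-level
#' baseline offsets (tissue, subject) dominating the temporal signal.
#'
#' @inheritParams coefficient_of_variation
#' @return data.frame with columns `gene`, `within_sd`, `between_sd`.
#' @export
within_between_sd <- function(expr, gene_set = NULL) {
  stopifnot(is_expression_matrix(expr))
  if (is.null(gene_set)) gene_set <- rownames(expr$values)
  series <- unique(expr$design$series_id)
  if (length(series) < 2L)
    stop("need at least 2 series to decompose within/between variability")
  idx <- lapply(series, function(s) which(expr$design$series_id == s))
  if (any(vapply(idx, length, 1L) < 2L))
    stop("every series needs at least 2 samples")
  v <- expr$values[gene_set, , drop = FALSE]
  within <- rowMeans(vapply(idx, function(i) apply(v[, i, drop = FALSE], 1L, stats::sd),
                            numeric(nrow(v))))
  means <- vapply(idx, function(i) rowMeans(v[, i, drop = FALSE]), numeric(nrow(v)))
  between <- apply(matrix(means, nrow = nrow(v)), 1L, stats::sd)
  data.frame(gene = gene_set, within_sd = unname(within),
             between_sd = unname(between), stringsAsFactors = FALSE)
}

#' Functional-cohesion enrichment score of a target set
#'
#' For every annotation category represented in the target set, the
#' hypergeometric upper-tail p-value of the overlap between the target set
#' and the category within the universe; the enrichment score is the sum of
#' `-log10(p)` over those categories. A biologically coherent target set —
#' many members sharing few categories — scores high; a random draw scores
#' near 0 because each of its categories has p close to 1.
#'
#' @param target_set character vector of predicted target gene ids.
#' @param annotation data.frame with columns `gene`, `category` (a gene may
#'   carry several categories).
#' @param universe character vector of all candidate genes (default: all
#'   annotated genes). Targets must lie within it.
#' @param p_adjust optional multiple-testing correction method (see
#'   [stats::p.adjust()]) applied to the per-category p-values before
#'   summing; the default `"none"` is the score as classically defined.
#' @return a list of class `EnrichmentResult`: `score`, `table`
#'   (data.frame: `category`, `overlap`, `category_size`, `p_value`).
#' @export
enrichment_score <- function(target_set, annotation, universe = NULL,
                             p_adjust = "none") {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(annotation)))
    stop("annotation needs columns `gene` and `category`")
  if (is.null(universe)) universe <- unique(annotation$gene)
  universe <- unique(as.character(universe))
  target_set <- unique(as.character(target_set))
  bad <- setdiff(target_set, universe)
  if (length(bad))
    stop("target set outside universe: ", paste(utils::head(bad, 5L), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  if (length(target_set) == 0L) {
    warning("empty target set: enrichment score is 0")
    return(structure(list(score = 0,
                          table = data.frame(category = character(),
                                             overlap = integer(),
                                             category_size = integer(),
                                             p_value = numeric())),
                     class = "EnrichmentResult"))
  }
  cats <- unique(ann$category[ann$gene %in% target_set])
  N <- length(universe); k <- length(target_set)
  tab <- do.call(rbind, lapply(cats, function(cc) {
    members <- unique(ann$gene[ann$category == cc])
    m <- length(members)
    q <- length(intersect(members, target_set))
    # upper tail: P(overlap >= q) drawing k from N with m in the category
    p <- stats::phyper(q - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(category = cc, overlap = q, category_size = m, p_value = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(category = character(), overlap = integer(),
                      category_size = integer(), p_value = numeric())
  p <- stats::p.adjust(tab$p_value, method = p_adjust)
  structure(list(score = sum(-log10(p)), table = tab),
            class = "EnrichmentResult")
}

#' Recall of gold-standard edges in the top fraction of predictions
#'
#' The fraction of gold-standard positive pairs found among the top
#' `ceiling(fraction * n_edges)` edges of a ranked edge list.
#'
#' @param ranked_edges data.frame from [rank_edges()] (columns `regulator`,
#'   `target`, ordered best first).
#' @param gold a [gold_standard()] (pairs `gold$regulator` -> positives) or
#'   a data.frame of positive pairs with columns `regulator`, `target`.
#' @param fraction number in (0, 1].
#' @return recall in [0, 1].
#' @export
recall_at_fraction <- function(ranked_edges, gold, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  pos <- if (inherits(gold, "GoldStandard")) {
    data.frame(regulator = gold$regulator, target = gold$positives,
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(gold, stringsAsFactors = FALSE)
  }
  if (!all(c("regulator", "target") %in% names(pos)))
    stop("gold pairs need columns `regulator` and `target`")
  if (nrow(pos) == 0L) stop("empty gold standard")
  covered <- paste(ranked_edges$regulator, ranked_edges$target, sep = "\r")
  want <- paste(pos$regulator, pos$target, sep = "\r")
  miss <- setdiff(want, covered)
  if (length(miss))
    stop("ranked edges do not cover ", length(miss), " gold pair(s)")
  top <- covered[seq_len(ceiling(fraction * length(covered)))]
  mean(want %in% top)
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives / %d targets)\n",
              x$auc, x$n_positive, x$n_universe))
  invisible(x)
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Enrichment score = %.3f over %d categories\n",
              x$score, nrow(x$table)))
  invisible(x)
}
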