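# Independent brute-force oracles the fast implementations are checked
# against. These deliberately use naive enumeration, never the package's
# own code paths.

# smaller-tail empirical p-value by direct counting
oracle_tail_p <- function(slope, background) {
  n_le <- sum(background <= slope)
  n_ge <- sum(background >= slope)
  (min(n_le, n_ge) + 1) / (length(background) + 1)
}

# ROC AUC by exhaustive pairwise comparison (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# hypergeometric upper tail P(X >= q) by direct combinatorial summation
oracle_hyper_upper <- function(q, m, N, k) {
  xs <- q:min(m, k)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# small multi-series expression fixture built in code
toy_expression <- function(values = NULL, times = c(0, 2, 4, 6),
                           n_series = 2, cyclic = FALSE, genes = 3,
                           seed = 42) {
  n <- length(times) * n_series
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(runif(genes * n, 1, 10), genes, n)
  }
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  design <- data.frame(
    sample_id = colnames(values),
    series_id = rep(paste0("ser", seq_len(n_series)), each = length(times)),
    time = rep(times, n_series), cyclic = cyclic)
  expression_matrix(values, design)
}

# per-regulator planted-edge AUCs for a synthetic dataset
planted_aucs <- function(dataset, edge_scores, use_nominal = FALSE) {
  uni <- colnames(edge_scores$scores)
  truth <- if (use_nominal) dataset$params else dataset$true_edges
  vapply(dataset$regulators, function(r) {
    pos <- setdiff(intersect(truth$target[truth$regulator == r], uni), r)
    gs <- gold_standard(r, pos, setdiff(uni, r))
    roc_auc(edge_scores$scores[r, setdiff(uni, r)], gs)$auc
  }, numeric(1L))
}
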