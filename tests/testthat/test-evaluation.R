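test_that("ROC AUC reproduces the worked examples", {
  gs <- gold_standard("tf", c("t1", "t2"), paste0("t", 1:4))
  expect_equal(roc_auc(c(t1 = 0.9, t2 = 0.8, t3 = 0.1, t4 = 0.05), gs)$auc, 1)
  # all scores equal: exactly 0.5 by the tie convention
  expect_equal(roc_auc(c(t1 = 1, t2 = 1, t3 = 1, t4 = 1), gs)$auc, 0.5)
  # positives are the 1st- and 3rd-ranked targets: 3 of 4 pairs ordered
  gs2 <- gold_standard("tf", c("t1", "t2"), paste0("t", 1:4))
  s2 <- c(t1 = 0.9, t2 = 0.3, t3 = 0.5, t4 = 0.1)
  expect_equal(roc_auc(s2, gs2)$auc, 0.75)
  expect_equal(oracle_auc(s2, names(s2) %in% c("t1", "t2")), 0.75)
  # reversed perfect ranking gives 0
  expect_equal(roc_auc(c(t1 = 0.1, t2 = 0.05, t3 = 0.8, t4 = 0.9), gs)$auc, 0)
  expect_error(roc_auc(c(t1 = 1, t2 = 2, t3 = 3, t4 = 4),
                       gold_standard("tf", paste0("t", 1:4), paste0("t", 1:4))),
               "tf")
})

test_that("AUC matches the pairwise oracle and pROC on random instances", {
  set.seed(41)
  has_proc <- requireNamespace("pROC", quietly = TRUE)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    uni <- paste0("t", seq_len(n))
    s <- setNames(sample(round(runif(n), sample(1:3, 1))), uni)  # forces ties
    np <- sample(seq_len(n - 1), 1)
    pos <- sample(uni, np)
    gs <- gold_standard("tf", pos, uni)
    auc <- roc_auc(s, gs)$auc
    expect_equal(auc, oracle_auc(s, uni %in% pos))
    if (has_proc && i <= 50)
      expect_equal(auc,
                   as.numeric(pROC::auc(pROC::roc(uni %in% pos, unname(s),
                                                  quiet = TRUE,
                                                  direction = "<"))))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  uni <- paste0("t", 1:30)
  s <- setNames(runif(30), uni)
  gs <- gold_standard("tf", sample(uni, 10), uni)
  a <- roc_auc(s, gs)$auc
  expect_equal(roc_auc(exp(5 * s), gs)$auc, a)
  expect_equal(roc_auc(rank(s), gs)$auc, a)
})

test_that("precision-recall curve and average precision", {
  gs <- gold_standard("tf", c("t1", "t2"), paste0("t", 1:4))
  pr <- pr_curve(c(t1 = 0.9, t2 = 0.8, t3 = 0.1, t4 = 0.05), gs)
  expect_equal(pr$average_precision, 1)
  expect_equal(pr$curve$precision[pr$curve$recall == 1][1], 1)
  # uninformative all-equal scores: AP equals the positive rate
  expect_equal(pr_curve(c(t1 = 1, t2 = 1, t3 = 1, t4 = 1),
                        gs)$average_precision, 0.5)
  # positives at ranks 1 and 3: AP = (1/1 + 2/3) / 2
  gs2 <- gold_standard("tf", c("t1", "t3"), paste0("t", 1:4))
  expect_equal(pr_curve(c(t1 = 0.9, t2 = 0.5, t3 = 0.3, t4 = 0.1),
                        gs2)$average_precision, (1 + 2 / 3) / 2)
})

test_that("coefficient of variation is sd/mean and scale-free", {
  v <- rbind(g1 = c(2, 2, 2, 2), g2 = c(1, 3, 1, 3), g3 = c(0, 0, 0, 0))
  colnames(v) <- paste0("s", 1:4)
  em <- expression_matrix(v, data.frame(sample_id = paste0("s", 1:4),
                                        series_id = rep(c("a", "b"), each = 2),
                                        time = c(0, 1, 0, 1)))
  expect_warning(cv <- coefficient_of_variation(em), "zero mean.*g3")
  expect_equal(unname(cv["g1"]), 0)
  expect_equal(unname(cv["g2"]), sd(c(1, 3, 1, 3)) / 2)
  expect_false("g3" %in% names(cv))
  # two-point formula and 10x rescale invariance
  expect_equal(sd(c(1, 3)) / 2, sqrt(2) / 2)
  em10 <- expression_matrix(v[1:2, ] * 10, em$design)
  expect_equal(coefficient_of_variation(em10), cv[1:2])
})

test_that("within/between-series SD decomposition", {
  v <- rbind(g1 = c(1, 1, 1, 5, 5, 5), g2 = c(1, 3, 1, 1, 3, 1))
  colnames(v) <- paste0("s", 1:6)
  d <- data.frame(sample_id = paste0("s", 1:6),
                  series_id = rep(c("a", "b"), each = 3),
                  time = rep(0:2, 2))
  em <- expression_matrix(v, d)
  wb <- within_between_sd(em)
  expect_equal(wb$within_sd[1], 0)
  expect_equal(wb$between_sd[1], sd(c(1, 5)))
  expect_equal(wb$between_sd[2], 0)
  expect_equal(wb$within_sd[2], sd(c(1, 3, 1)))
  # shifting one whole series changes only the between component
  v2 <- v; v2[, 4:6] <- v2[, 4:6] + 7
  wb2 <- within_between_sd(expression_matrix(v2, d))
  expect_equal(wb2$within_sd, wb$within_sd)
  expect_false(isTRUE(all.equal(wb2$between_sd, wb$between_sd)))
  # single series is an error
  d1 <- transform(d, series_id = "a", time = 0:5)
  expect_error(within_between_sd(expression_matrix(v, d1)), "2 series")
})

test_that("enrichment reproduces the exact hypergeometric examples", {
  uni <- paste0("g", 1:20)
  ann <- data.frame(gene = uni[1:10], category = "cat1")
  res <- enrichment_score(uni[1:10], ann, uni)
  expect_equal(res$table$p_value, 1 / choose(20, 10))
  expect_equal(res$score, -log10(1 / choose(20, 10)))
  expect_equal(res$score, 5.267, tolerance = 1e-3)
  # two categories with p 0.1 and 0.01 would sum to 3
  expect_equal(sum(-log10(c(0.1, 0.01))), 3)
  # a target set matching category proportions scores ~0
  ann2 <- data.frame(gene = uni, category = rep(c("a", "b"), 10))
  res2 <- enrichment_score(uni[1:8], ann2, uni)
  expect_lt(res2$score, 1)
  expect_warning(res0 <- enrichment_score(character(), ann2, uni), "empty")
  expect_equal(res0$score, 0)
})

test_that("hypergeometric p-values match direct summation on small universes", {
  set.seed(12)
  for (i in 1:100) {
    N <- sample(5:30, 1)
    uni <- paste0("g", seq_len(N))
    m <- sample(2:(N - 1), 1)
    ann <- data.frame(gene = uni[seq_len(m)], category = "c")
    k <- sample(seq_len(N - 1), 1)
    targets <- sample(uni, k)
    res <- enrichment_score(targets, ann, uni)
    q <- length(intersect(targets, uni[seq_len(m)]))
    if (q == 0) {
      expect_identical(nrow(res$table), 0L)
    } else {
      expect_equal(res$table$p_value, oracle_hyper_upper(q, m, N, k))
    }
  }
})

test_that("recall at a top fraction of ranked edges", {
  edges <- data.frame(regulator = "A", target = paste0("t", 1:10),
                      score = 10:1)
  gold <- data.frame(regulator = "A", target = c("t1", "t2"))
  expect_equal(recall_at_fraction(edges, gold, 0.2), 1)
  expect_equal(recall_at_fraction(edges, gold, 0.15), 1)  # ceiling(1.5) = 2
  gold2 <- data.frame(regulator = "A", target = c("t9", "t10"))
  expect_equal(recall_at_fraction(edges, gold2, 0.1), 0)
  expect_error(recall_at_fraction(edges, gold, 0), "fraction")
  expect_error(recall_at_fraction(edges,
    data.frame(regulator = "A", target = "zz"), 0.5), "cover")
  # non-decreasing in fraction
  set.seed(3)
  eb <- data.frame(regulator = "A", target = paste0("t", 1:40),
                   score = runif(40))
  eb <- eb[order(-eb$score), ]
  goldb <- data.frame(regulator = "A", target = sample(eb$target, 8))
  r <- vapply(seq(0.05, 1, by = 0.05), recall_at_fraction,
              numeric(1), ranked_edges = eb, gold = goldb)
  expect_true(all(diff(r) >= 0))
})

test_that("random uniform scores give expected recall ~ fraction", {
  set.seed(60)
  rec <- vapply(1:200, function(i) {
    e <- data.frame(regulator = "A", target = paste0("t", 1:50),
                    score = runif(50))
    e <- e[order(-e$score), ]
    gold <- data.frame(regulator = "A", target = paste0("t", 1:10))
    recall_at_fraction(e, gold, 0.1)
  }, numeric(1))
  expect_equal(mean(rec), 0.1, tolerance = 0.25)
})
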