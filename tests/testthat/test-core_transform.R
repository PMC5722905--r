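direct_cfg <- transform_config(bootstrap = FALSE)

test_that("slopes over consecutive steps match direct arithmetic", {
  v <- matrix(c(1, 3, 2), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  em <- expression_matrix(v, data.frame(sample_id = paste0("s", 1:3),
                                        series_id = "a", time = c(0, 2, 4)))
  ss <- compute_slopes(em, direct_cfg)
  expect_equal(unname(ss$slopes[1, ]), c(1, -0.5))
  expect_equal(ss$steps$from_time, c(0, 2))
  expect_equal(unname(ss$signs[1, ]), c(1, -1))
})

test_that("a cyclic constant series yields an extra wrap step of slope 0", {
  v <- matrix(5, 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  em <- expression_matrix(v, data.frame(sample_id = paste0("s", 1:3),
                                        series_id = "a", time = c(0, 2, 4),
                                        cyclic = TRUE))
  ss <- compute_slopes(em, transform_config(bootstrap = FALSE, wrap_interval = 2))
  expect_equal(ncol(ss$slopes), 3L)
  expect_equal(unname(ss$slopes[1, ]), c(0, 0, 0))
  expect_equal(unname(ss$signs[1, ]), c(0, 0, 0))
  expect_true(ss$steps$wrap[3])
  # wrap interval defaults to the median within-series gap
  ss2 <- compute_slopes(em, direct_cfg)
  expect_equal(ss2$steps$dt[3], 2)
})

test_that("steps never pair samples from different series", {
  em <- toy_expression(times = c(0, 2, 4, 6), n_series = 2)
  em2 <- toy_expression(times = c(0, 3, 6), n_series = 1)
  # two series of lengths 4 and 3: exactly 3 + 2 = 5 steps
  v <- cbind(em$values[1:2, 1:4], em2$values[1:2, ] + 1)
  colnames(v) <- paste0("s", 1:7)
  d <- data.frame(sample_id = paste0("s", 1:7),
                  series_id = rep(c("a", "b"), c(4, 3)),
                  time = c(0, 2, 4, 6, 0, 3, 6))
  ss <- compute_slopes(expression_matrix(v, d), direct_cfg)
  expect_equal(ncol(ss$slopes), 5L)
  expect_false(any(with(ss$steps,
    tapply(series_id, seq_along(series_id), identity) !=
    sub(":.*", "", colnames(ss$slopes)))))
  same_series <- d$series_id[match(ss$steps$from_sample, d$sample_id)] ==
    d$series_id[match(ss$steps$to_sample, d$sample_id)]
  expect_true(all(same_series))
})

test_that("series with fewer than 2 samples is an error naming the series", {
  v <- matrix(1:3, 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  d <- data.frame(sample_id = paste0("s", 1:3),
                  series_id = c("a", "a", "lonely"), time = c(0, 2, 0))
  expect_error(compute_slopes(expression_matrix(v, d), direct_cfg), "lonely")
})

test_that("background resampling is closed, deterministic and sized", {
  pooled <- c(-1, 0, 1)
  cfg <- transform_config(bootstrap = TRUE, bootstrap_reps = 9, seed = 5)
  b1 <- build_background(pooled, cfg)
  b2 <- build_background(pooled, cfg)
  expect_length(b1$reference, 9L)
  expect_true(all(b1$reference %in% pooled))
  expect_identical(b1$reference, b2$reference)
  expect_false(identical(
    b1$reference, build_background(pooled, cfg, stream = 1L)$reference))
  # degenerate background: all draws are the single pooled value
  expect_true(all(build_background(rep(5, 4), cfg)$reference == 5))
  # direct mode keeps the pooled multiset: 12 series x 24 cyclic steps = 288
  pooled288 <- rnorm(288)
  expect_length(build_background(pooled288, direct_cfg)$reference, 288L)
  expect_error(build_background(numeric(0), cfg), "empty")
})

test_that("tail p-values equal the counting oracle on the worked examples", {
  bg <- c(-2, -1, 0, 1, 2)
  expect_equal(tail_pvalue(2, bg), 2 / 6)
  expect_equal(tail_pvalue(0, bg), 4 / 6)
  expect_equal(tail_pvalue(10, bg), 1 / 6)   # smoothing floor, never 0
  expect_equal(tail_pvalue(c(2, 0, 10), bg), c(2, 4, 1) / 6)
})

test_that("tail p-values match exhaustive counting on random backgrounds", {
  set.seed(900)
  for (i in 1:200) {
    bg <- sample(round(rnorm(sample(2:20, 1)), 1), replace = TRUE)
    s <- round(rnorm(5, sd = 2), 1)
    expect_equal(tail_pvalue(s, bg),
                 vapply(s, oracle_tail_p, 1, background = bg))
  }
})

test_that("RANGES combines -log10 p with the slope sign", {
  # one gene whose slope multiset is {-2,-1,0,1,2} exactly: p(2)=2/6 up
  v <- matrix(cumsum(c(5, -2, -1, 0, 1, 2)), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  em <- expression_matrix(v, data.frame(sample_id = paste0("s", 1:6),
                                        series_id = "a", time = 0:5))
  R <- ranges(em, direct_cfg)
  expect_equal(unname(R$values[1, ]),
               -log10(c(2, 3, 4, 3, 2) / 6) * c(-1, -1, 0, 1, 1))
  expect_equal(unname(R$values[1, 1]), -(-log10(2 / 6)))
  expect_equal(-log10(2 / 6), 0.4771213, tolerance = 1e-6)
  # slope exactly 0 gives R = 0
  expect_equal(unname(R$values[1, 3]), 0)
})

test_that("the literal larger-tail form caps |R| at log10(2)", {
  em <- toy_expression(genes = 4, seed = 3)
  Rlit <- ranges(em, transform_config(bootstrap = FALSE, tail = "literal"))
  expect_true(all(abs(Rlit$values) <= log10(2) + 1e-12))
  Rsm <- ranges(em, direct_cfg)
  expect_gt(max(abs(Rsm$values)), log10(2))
})

test_that("sign coherence holds on randomized inputs", {
  for (seed in 1:5) {
    em <- toy_expression(genes = 5, seed = seed, n_series = 2,
                         cyclic = seed %% 2 == 0)
    ss <- compute_slopes(em, direct_cfg)
    R <- ranges(em, direct_cfg)
    expect_identical(sign(R$values), ss$signs)
  }
})

test_that("RANGES is invariant to per-gene expression scale and time units", {
  em <- toy_expression(genes = 4, seed = 11, n_series = 2)
  cfg <- transform_config(bootstrap = TRUE, bootstrap_reps = 500, seed = 2)
  R <- ranges(em, cfg)
  # per-gene positive rescaling
  v2 <- em$values * c(3, 0.5, 10, 1)
  em2 <- expression_matrix(v2, em$design)
  expect_equal(ranges(em2, cfg)$values, R$values)
  # global positive rescaling of all time values
  d3 <- em$design; d3$time <- d3$time * 60
  em3 <- expression_matrix(em$values, d3)
  expect_equal(unname(ranges(em3, cfg)$values), unname(R$values))
  # ExRANGES scales linearly with per-gene expression rescaling
  E <- exranges(em, R)
  E2 <- exranges(em2, ranges(em2, cfg))
  expect_equal(E2$values, E$values * c(3, 0.5, 10, 1))
})

test_that("|R| grows with distance from the background median", {
  bg <- sort(rnorm(15))
  s <- seq(min(bg) - 1, max(bg) + 1, length.out = 41)
  p <- tail_pvalue(s, bg)
  med <- median(bg)
  below <- s < med & p < 0.5   # outside the inter-tail tie region
  above <- s > med & p < 0.5
  expect_true(all(diff(-log10(p[below])) <= 1e-12))
  expect_true(all(diff(-log10(p[above])) >= -1e-12))
})

test_that("step counts follow the shape law over random designs", {
  set.seed(77)
  for (i in 1:10) {
    ns <- sample(1:4, 1)
    lens <- sample(2:8, ns, replace = TRUE)
    cyc <- sample(c(TRUE, FALSE), ns, replace = TRUE)
    v <- matrix(runif(2 * sum(lens)), 2, sum(lens),
                dimnames = list(c("g1", "g2"), paste0("s", seq_len(sum(lens)))))
    d <- data.frame(sample_id = colnames(v),
                    series_id = rep(paste0("ser", 1:ns), lens),
                    time = unlist(lapply(lens, seq_len)),
                    cyclic = rep(cyc, lens))
    ss <- compute_slopes(expression_matrix(v, d), direct_cfg)
    expect_equal(ncol(ss$slopes), sum(lens - 1L + cyc))
    R <- ranges(expression_matrix(v, d), direct_cfg)
    expect_equal(dim(R$values), c(2L, sum(lens - 1L + cyc)))
  }
})

test_that("the transform is deterministic under a fixed seed", {
  em <- toy_expression(genes = 3, seed = 8)
  cfg <- transform_config(bootstrap = TRUE, bootstrap_reps = 1000, seed = 99)
  expect_identical(ranges(em, cfg)$values, ranges(em, cfg)$values)
})

test_that("ExRANGES is the product with expression at the step start", {
  em <- toy_expression(genes = 3, seed = 4, times = c(0, 2, 4), n_series = 2)
  R <- ranges(em, direct_cfg)
  E <- exranges(em, R)
  expect_identical(dim(E$values), dim(R$values))
  expect_equal(E$values,
               R$values * em$values[, R$steps$from_sample])
  expect_true(all(E$values[R$values == 0] == 0))
  # non-cyclic series of N samples contribute N - 1 step columns
  expect_equal(ncol(E$values), 2 * 2)
  # mismatched genes are an error
  emx <- toy_expression(genes = 4, seed = 4, times = c(0, 2, 4), n_series = 2)
  expect_error(exranges(emx, R), "gene sets")
})
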