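test_that("trend discretization reduces profiles to their step signs", {
  expect_identical(discretize_trend(rbind(c(1, 2, 2, 1.5), c(0, 1, 2, 3))),
                   rbind(c(1L, 0L, -1L), c(1L, 1L, 1L)))
  x <- random_expr(3, 4, 8)
  b <- discretize_trend(x)
  V <- x$values
  for (i in 1:4) for (j in 1:7)
    expect_identical(b[i, j], as.integer(sign(V[i, j + 1] - V[i, j])))
})

test_that("trend score is 1 for consistently parallel AND contrary monotone pairs", {
  up <- seq_len(6)
  b <- discretize_trend(rbind(up, up))
  expect_equal(trend_score(b, 1, 2, 0), 1)
  b2 <- discretize_trend(rbind(up, rev(up)))
  expect_equal(trend_score(b2, 1, 2, 0), 1)  # mirror-image trends co-move too
  expect_error(trend_score(b, 1, 2, 4), "P - 3")
})

test_that("the three features match independent literal-loop oracles", {
  n_checked <- 0L
  for (s in 1:40) {
    set.seed(1000 + s)
    N <- sample(2:6, 1)
    P <- sample(8:20, 1)
    V <- matrix(rnorm(N * P), N, P, dimnames = list(paste0("G", 1:N), NULL))
    x <- expr_ts(V)
    b <- discretize_trend(x)
    for (a in 0:2) {
      m <- sample(N, 1); n <- sample(N, 1)
      expect_equal(trend_score(b, m, n, a),
                   oracle_trend_score(b[m, ], b[n, ], a), tolerance = 1e-12)
      expect_equal(delay_correlation(x, m, n, a),
                   oracle_delay_cor(V[m, ], V[n, ], a), tolerance = 1e-12)
      expect_equal(delay_mutual_information(x, m, n, a, bins = 3),
                   oracle_delay_mi(V[m, ], V[n, ], a, bins = 3),
                   tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("lagged correlation honours its conventions", {
  # exact unit-lag copy
  set.seed(9)
  vm <- rnorm(20)
  V <- rbind(m = vm, n = c(0, vm[-20]))
  expect_equal(delay_correlation(V, 1, 2, 1), 1)
  # zero-variance segment convention
  V2 <- rbind(m = rnorm(10), n = rep(1, 10))
  expect_equal(delay_correlation(V2, 1, 2, 0), 0)
  # antisymmetry under negating one series
  x <- random_expr(21, 2, 15)
  for (a in 0:2)
    expect_equal(delay_correlation(x$values, 1, 2, a),
                 -delay_correlation(rbind(x$values[1, ], -x$values[2, ]), 1, 2, a),
                 tolerance = 1e-12)
  expect_error(delay_correlation(x$values, 1, 2, 13), "P - a")
})

test_that("mutual information is self-consistent, non-negative, relabel-invariant", {
  set.seed(31)
  v <- rnorm(16)
  V <- rbind(m = v, n = v)
  # a gene against itself carries exactly its own entropy
  mi <- delay_mutual_information(V, 1, 2, 0, bins = 3)
  lab <- cut(v, seq(min(v), max(v), length.out = 4), include.lowest = TRUE,
             labels = FALSE)
  p <- table(lab) / length(lab)
  expect_equal(mi, -sum(p * log2(p)), tolerance = 1e-12)

  # hand-counted 1-bit case: both series bin as 1,1,2,2
  V2 <- rbind(m = c(0, 0, 1, 1), n = c(0, 0, 1, 1))
  expect_equal(delay_mutual_information(V2, 1, 2, 0, bins = 2), 1)

  # negating a series permutes its bin labels; MI is unchanged
  x <- random_expr(32, 2, 15)
  for (a in 0:2)
    expect_equal(delay_mutual_information(x$values, 1, 2, a),
                 delay_mutual_information(rbind(x$values[1, ], -x$values[2, ]),
                                          1, 2, a),
                 tolerance = 1e-12)

  # zero-range gene: zero entropy, zero information, not an error
  V3 <- rbind(m = rnorm(8), n = rep(2, 8))
  expect_equal(delay_mutual_information(V3, 1, 2, 1), 0)
})

test_that("the flattened feature table has the documented order and content", {
  x <- random_expr(7, 2, 8)
  f <- assemble_features(x, max_delay = 1)
  expect_identical(nrow(f), 8L)  # 2^2 pairs x 2 delay levels
  expect_identical(f$gene_m, rep(x$gene_ids, each = 4))
  expect_identical(f$delay, rep(0:1, 4))

  f2 <- assemble_features(x, max_delay = 1, include_self = FALSE)
  expect_identical(nrow(f2), 4L)  # N(N-1) x (A+1)

  # delay-0 sub-table is symmetric under pair transposition
  y <- random_expr(8, 4, 12)
  g <- assemble_features(y, max_delay = 2)
  a0 <- g[g$delay == 0, ]
  for (r in seq_len(nrow(a0))) {
    mirror <- a0[a0$gene_m == a0$gene_n[r] & a0$gene_n == a0$gene_m[r], ]
    expect_equal(mirror$trend_score, a0$trend_score[r])
    expect_equal(mirror$correlation, a0$correlation[r])
    expect_equal(mirror$mutual_information, a0$mutual_information[r])
  }

  # every cell equals per-pair recomputation by the single-pair operations
  b <- discretize_trend(y)
  idx <- match(g$gene_m, y$gene_ids)
  jdx <- match(g$gene_n, y$gene_ids)
  for (r in seq_len(nrow(g))) {
    expect_equal(g$trend_score[r], trend_score(b, idx[r], jdx[r], g$delay[r]))
    expect_equal(g$correlation[r],
                 delay_correlation(y, idx[r], jdx[r], g$delay[r]))
    expect_equal(g$mutual_information[r],
                 delay_mutual_information(y, idx[r], jdx[r], g$delay[r], 3))
  }

  # feature ranges
  expect_true(all(g$trend_score >= 0 & g$trend_score <= 1))
  expect_true(all(abs(g$correlation) <= 1))
  expect_true(all(g$mutual_information >= 0))
  expect_error(assemble_features(y, max_delay = 10), "P - 3")
})
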