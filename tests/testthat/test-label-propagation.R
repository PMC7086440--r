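test_that("the RBF kernel graph has the prescribed similarities", {
  # two identical feature triples (distinct samples) -> kernel exactly 1
  X <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))
  f <- fake_features(X, gene_m = c("a", "a", "b", "b"),
                     gene_n = c("b", "c", "c", "a"),
                     delay = c(0, 0, 0, 0), genes = c("a", "b", "c"))
  g <- build_graph(f, k_neighbors = 2, sigma = 1)
  expect_equal(g$W[1, 2], 1)
  expect_identical(unname(diag(g$W)), rep(0, 4))  # a sample with itself -> 0
  expect_true(all(g$W >= 0 & g$W <= 1))
  expect_identical(unname(rowSums(g$knn)), rep(2, 4))

  # closed form: d = sigma * sqrt(2) -> kernel exp(-1)
  X2 <- cbind(c(0, sqrt(2)), c(0, 0), c(0, 0))
  f2 <- fake_features(X2, gene_m = c("a", "b"), gene_n = c("b", "a"),
                      delay = c(0, 0), genes = c("a", "b"))
  g2 <- build_graph(f2, k_neighbors = 1, sigma = 1)
  expect_equal(g2$W[1, 2], exp(-1), tolerance = 1e-12)

  expect_error(build_graph(f, k_neighbors = 2, sigma = -1), "sigma")
  expect_error(build_graph(f, k_neighbors = 5), "k_neighbors \\+ 1")
})

test_that("propagation resolves the trivial symmetric and absorbing cases", {
  # path seed(+) -- u -- seed(-) with equal similarities: u stays undecided
  X <- cbind(c(0, 1, 2), 0, 0)
  f <- fake_features(X, gene_m = c("a", "a", "b"), gene_n = c("b", "c", "c"),
                     delay = c(0, 0, 0), genes = c("a", "b", "c"))
  g <- build_graph(f, k_neighbors = 1, sigma = 1)
  st <- propagate(g, data.frame(sample = c(1, 3), label = c(1, -1)))
  expect_equal(st$membership[2, ], c(0.5, 0.5))
  expect_equal(st$decision[2], 0)

  # an unlabeled sample whose every neighbour is a class-1 seed is absorbed
  X3 <- cbind(c(0, 1, 0.5, 10), 0, 0)
  f3 <- fake_features(X3, gene_m = c("a", "a", "b", "b"),
                      gene_n = c("b", "c", "c", "a"),
                      delay = c(0, 0, 0, 1), genes = c("a", "b", "c"))
  g3 <- build_graph(f3, k_neighbors = 2, sigma = 1)
  st3 <- propagate(g3, data.frame(sample = c(1, 2, 4), label = c(1, 1, -1)),
                   tol = 1e-12)
  expect_equal(st3$membership[3, ], c(1, 0), tolerance = 1e-9)

  # seeds must cover both classes
  expect_error(propagate(g, data.frame(sample = 1, label = 1)), "each class")
})

test_that("converged memberships equal the clamped harmonic extension", {
  n_graphs <- 0L
  s <- 0L
  while (n_graphs < 20L) {
    s <- s + 1L
    set.seed(5000 + s)
    n <- sample(15:50, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    f <- fake_features(X, gene_m = rep("a", n), gene_n = rep("b", n),
                       delay = seq_len(n), genes = c("a", "b"))
    g <- build_graph(f, k_neighbors = 5, sigma = "auto")
    if (!graph_is_connected(g$W)) next
    n_graphs <- n_graphs + 1L
    n_seed <- sample(2:5, 1)
    idx <- sample(n, n_seed)
    lab <- c(1L, -1L, sample(c(1L, -1L), n_seed - 2L, replace = TRUE))
    st <- propagate(g, data.frame(sample = idx, label = lab),
                    tol = 1e-13, max_iter = 100000)
    direct <- harmonic_solve(g$W, idx, lab)
    expect_lt(max(abs(st$membership - direct)), 1e-8)
    # seed rows bitwise unchanged from initialization
    expect_identical(st$membership[idx, , drop = FALSE],
                     cbind(as.numeric(lab == 1), as.numeric(lab == -1)))
    # all rows on the simplex
    expect_true(all(st$membership >= -1e-12 & st$membership <= 1 + 1e-12))
    expect_equal(unname(rowSums(st$membership)), rep(1, n), tolerance = 1e-9)
  }
})

test_that("edge decoding applies thresholding, per-pair argmax and tie rules", {
  genes <- c("a", "b")
  f <- fake_features(matrix(0, 6, 3),
                     gene_m = rep(c("a", "b"), each = 3),
                     gene_n = rep(c("b", "a"), each = 3),
                     delay = rep(0:2, 2), genes = genes)
  pick <- function(dec) decide_edges(fake_state(dec), f)

  e <- pick(c(0.2, 0.6, -0.1, -1, -1, -1))
  expect_identical(e$delay, 1L)
  expect_identical(e$regulator, "a")
  expect_equal(e$decision_value, 0.6)

  expect_identical(nrow(pick(c(-0.3, -0.1, 0, -1, -1, -1))), 0L)  # all zeroed

  e3 <- pick(c(0.5, 0.5, 0.1, -1, -1, -1))
  expect_identical(e3$delay, 0L)  # tie goes to the smallest delay

  # orientation tie at equal decision goes to canonical input order
  e4 <- pick(c(0.4, -1, -1, 0.4, -1, -1))
  expect_identical(e4$regulator, "a")

  # reversed-orientation maximum flips the reported direction
  e5 <- pick(c(-1, 0.2, -1, -1, 0.7, -1))
  expect_identical(e5$regulator, "b")
  expect_identical(e5$delay, 1L)
})

test_that("decoding never emits self-edges or duplicate pairs", {
  x <- random_expr(44, 5, 14)
  f <- assemble_features(x, max_delay = 2)
  set.seed(44)
  st <- fake_state(runif(nrow(f), -1, 1))
  e <- decide_edges(st, f)
  expect_true(all(e$regulator != e$target))
  key <- paste(pmin(e$regulator, e$target), pmax(e$regulator, e$target))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(e$decision_value > 0))
})
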