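# Independent literal-loop oracles used to cross-check the package's
# vectorized implementations. These deliberately re-derive every quantity
# with naive loops and stock R functions rather than calling package code.

oracle_trend_score <- function(bm, bn, a) {
  P <- length(bm) + 1L
  bp <- numeric(P - 1L - a)
  for (j in seq_len(P - 1L - a)) bp[j] <- bm[j] * bn[j + a]
  s <- numeric(P - 2L - a)
  for (j in seq_len(P - 2L - a)) s[j] <- bp[j] * bp[j + 1L]
  sum(s == 1) / (P - 2L - a)
}

oracle_delay_cor <- function(xm, xn, a) {
  P <- length(xm)
  stats::cor(xm[seq_len(P - a)], xn[seq.int(1L + a, P)])
}

oracle_delay_mi <- function(xm, xn, a, bins) {
  P <- length(xm)
  lab <- function(full, seg) {
    if (min(full) == max(full)) return(rep(1L, length(seg)))
    cut(seg, breaks = seq(min(full), max(full), length.out = bins + 1L),
        include.lowest = TRUE, labels = FALSE)
  }
  u <- lab(xm, xm[seq_len(P - a)])
  v <- lab(xn, xn[seq.int(1L + a, P)])
  n <- length(u)
  H <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log2(p))
  }
  H(table(u)) + H(table(v)) - H(table(paste(u, v)))
}

oracle_impute <- function(V, obs, k) {
  out <- V
  n <- nrow(V)
  for (i in seq_len(n)) for (j in seq_len(ncol(V))) {
    if (obs[i, j]) next
    ds <- numeric(0); rows <- integer(0)
    for (r in seq_len(n)[-i]) {
      sh <- which(obs[i, ] & obs[r, ])
      if (length(sh) && obs[r, j]) {
        ds <- c(ds, sqrt(sum((V[i, sh] - V[r, sh])^2)))
        rows <- c(rows, r)
      }
    }
    if (!length(rows)) {
      out[i, j] <- mean(V[i, obs[i, ]])
      next
    }
    o <- order(ds, rows)
    rows <- rows[o][seq_len(min(k, length(rows)))]
    ds <- ds[o][seq_len(min(k, length(ds)))]
    out[i, j] <- if (any(ds == 0)) mean(V[rows[ds == 0], j])
                 else sum(V[rows, j] / ds) / sum(1 / ds)
  }
  out
}

# Fixed point of clamped label propagation, solved directly: unlabeled rows
# satisfy (D - W)_uu F_u = W_ul F_l (harmonic extension).
harmonic_solve <- function(W, seed_idx, seed_lab) {
  n <- nrow(W)
  Fm <- matrix(0, n, 2L)
  Fm[seed_idx, ] <- cbind(as.numeric(seed_lab == 1), as.numeric(seed_lab == -1))
  u <- setdiff(seq_len(n), seed_idx)
  A <- diag(rowSums(W)[u], nrow = length(u)) - W[u, u, drop = FALSE]
  Fm[u, ] <- solve(A, W[u, seed_idx, drop = FALSE] %*% Fm[seed_idx, , drop = FALSE])
  Fm
}

graph_is_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  q <- 1L
  seen[1L] <- TRUE
  while (length(q)) {
    i <- q[1L]; q <- q[-1L]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    q <- c(q, nb)
  }
  all(seen)
}

# Minimal feature-table stand-in for exercising build_graph / decide_edges
# with hand-chosen coordinates.
fake_features <- function(scaled, gene_m, gene_n, delay, genes) {
  df <- data.frame(gene_m = gene_m, gene_n = gene_n, delay = delay,
                   stringsAsFactors = FALSE)
  structure(df, scaled = as.matrix(scaled), gene_ids = genes,
            max_delay = max(delay), include_self = FALSE,
            class = c("delay_features", "data.frame"))
}

fake_state <- function(decision) {
  m <- cbind((1 + decision) / 2, (1 - decision) / 2)
  structure(list(membership = m, clamped = rep(FALSE, length(decision)),
                 decision = decision, iterations = 1L, converged = TRUE),
            class = "fuzzy_labels")
}

random_expr <- function(seed, N, P) {
  set.seed(seed)
  m <- matrix(stats::rnorm(N * P), N, P,
              dimnames = list(paste0("G", seq_len(N)), NULL))
  expr_ts(m)
}
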