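#' Simulate a ground-truthed delayed gene regulatory network
#'
#' Emulates short cell-cycle-like chip time series: root genes (no
#' regulators) follow a sinusoid with a random period of 8-12 sampling
#' intervals and random phase; each regulated gene is the weighted sum of its
#' regulators' series, each shifted by that edge's delay, plus additive
#' Gaussian noise. Edges are oriented along a random gene ordering, so the
#' network is acyclic by construction and every target is computable from a
#' burn-in prefix that is discarded. A fraction `sign_mix` of edges gets a
#' negative weight, producing the contrary ("mirror-image") change trends
#' typical of repression. A fraction `missing_rate` of cells is masked
#' unobserved (each gene always keeps at least two observed values).
#' Identical `seed` gives identical output.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Series length P.
#' @param n_edges Number of true regulations (distinct unordered pairs).
#' @param max_delay Maximum per-edge delay A, in sampling intervals.
#' @param edge_weight_range Range of absolute regulation weights.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   expression units (root sinusoids have amplitude 1).
#' @param missing_rate Fraction of cells masked unobserved, in \[0, 1).
#' @param sign_mix Fraction of edges given a negative (repressing) weight.
#' @param seed Integer random seed.
#' @return List with `expr` (an [expr_ts]), `truth` (edge data frame with
#'   `regulator`, `target`, `delay`, `decision_value` = signed weight), and
#'   `spec` (the arguments as given).
#' @export
simulate_grn <- function(n_genes = 6, n_timepoints = 20, n_edges = 10,
                         max_delay = 2, edge_weight_range = c(0.5, 1),
                         noise_sd = 0.1, missing_rate = 0.05,
                         sign_mix = 0.3, seed = 1L) {
  P <- as.integer(n_timepoints)
  n_genes <- as.integer(n_genes)
  n_edges <- as.integer(n_edges)
  max_delay <- as.integer(max_delay)
  if (n_genes < 2L) stop("need at least 2 genes")
  if (n_edges < 1L || n_edges > choose(n_genes, 2L))
    stop("n_edges must lie in [1, n_genes(n_genes-1)/2]")
  if (max_delay < 0L || max_delay > P - 3L)
    stop("max_delay must lie in [0, P - 3]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  genes <- paste0("G", seq_len(n_genes))

  # orient edges along a random gene ordering: acyclic even at delay 0
  rank <- sample(n_genes)
  cmb <- utils::combn(n_genes, 2L)
  pick <- sort(sample(ncol(cmb), n_edges))
  reg <- tgt <- integer(n_edges)
  for (e in seq_len(n_edges)) {
    i <- cmb[1L, pick[e]]; j <- cmb[2L, pick[e]]
    if (rank[i] < rank[j]) { reg[e] <- i; tgt[e] <- j } else { reg[e] <- j; tgt[e] <- i }
  }
  delay <- sample(0:max_delay, n_edges, replace = TRUE)
  w <- stats::runif(n_edges, edge_weight_range[1L], edge_weight_range[2L])
  n_neg <- round(sign_mix * n_edges)
  if (n_neg > 0L) {
    negs <- sample(n_edges, n_neg)
    w[negs] <- -w[negs]
  }

  # burn-in long enough for the deepest chain of delayed dependencies
  B <- max_delay * n_genes
  Pext <- B + P
  X <- matrix(NA_real_, n_genes, Pext)
  first <- integer(n_genes)
  for (g in order(rank)) {
    inc <- which(tgt == g)
    if (length(inc) == 0L) {
      period <- stats::runif(1L, 8, 12)
      phase <- stats::runif(1L, 0, 2 * pi)
      X[g, ] <- sin(2 * pi * seq_len(Pext) / period + phase) +
        stats::rnorm(Pext, 0, noise_sd)
      first[g] <- 1L
    } else {
      first[g] <- max(first[reg[inc]] + delay[inc])
      tt <- seq.int(first[g], Pext)
      acc <- rep(0, length(tt))
      for (e in inc) acc <- acc + w[e] * X[reg[e], tt - delay[e]]
      X[g, tt] <- acc + stats::rnorm(length(tt), 0, noise_sd)
    }
  }
  V <- X[, seq.int(B + 1L, Pext), drop = FALSE]
  rownames(V) <- genes

  obs <- matrix(TRUE, n_genes, P)
  n_miss <- floor(missing_rate * n_genes * P)
  if (n_miss > 0L) {
    for (cell in sample(n_genes * P, n_miss)) {
      i <- (cell - 1L) %% n_genes + 1L
      j <- (cell - 1L) %/% n_genes + 1L
      if (sum(obs[i, ]) > 2L) obs[i, j] <- FALSE
    }
  }

  truth <- data.frame(regulator = genes[reg], target = genes[tgt],
                      delay = delay, decision_value = w,
                      stringsAsFactors = FALSE)
  truth <- truth[order(pmin(reg, tgt), pmax(reg, tgt)), , drop = FALSE]
  rownames(truth) <- NULL
  list(expr = expr_ts(V, observed = obs), truth = truth,
       spec = list(n_genes = n_genes, n_timepoints = P, n_edges = n_edges,
                   max_delay = max_delay,
                   edge_weight_range = edge_weight_range,
                   noise_sd = noise_sd, missing_rate = missing_rate,
                   sign_mix = sign_mix, seed = as.integer(seed)))
}

# Unordered pairs with no directed path between them in the truth network.
unrelated_pairs <- function(truth, genes) {
  n <- length(genes)
  reach <- matrix(FALSE, n, n)
  ri <- match(truth$regulator, genes)
  ti <- match(truth$target, genes)
  reach[cbind(ri, ti)] <- TRUE
  for (k in seq_len(n))  # transitive closure
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  cmb <- utils::combn(n, 2L)
  keep <- !(reach[cbind(cmb[1L, ], cmb[2L, ])] |
              reach[cbind(cmb[2L, ], cmb[1L, ])])
  data.frame(gene_m = genes[cmb[1L, keep]], gene_n = genes[cmb[2L, keep]],
             stringsAsFactors = FALSE)
}

#' Draw seed labels from a ground-truth network
#'
#' Samples `n_pos` true edges (labelled +1 at their true delay) and `n_neg`
#' negative pairs (labelled -1 at delay 0), reproducibly by `seed`. Both
#' classes are mandatory — label propagation cannot run one-sided. The
#' negative pool is by default every unordered non-edge; with
#' `neg_pool = "unrelated"` non-edges with no directed path between them in
#' the truth network are drawn first (falling back to the remaining
#' non-edges only when there are too few), emulating a curator who seeds
#' "no regulation" on genes known to be unrelated rather than on indirectly
#' coupled ones. With `balance_signs = TRUE` the positive seeds are
#' stratified across activating and repressing edges when both exist, so the
#' labelled set covers both regulation modes.
#'
#' @param truth Ground-truth edge data frame (`decision_value` carries the
#'   signed weight).
#' @param genes Character vector of all gene ids.
#' @param n_pos,n_neg Seeds per class (both >= 1).
#' @param seed Integer random seed.
#' @param neg_pool `"non_edge"` (default) or `"unrelated"`.
#' @param balance_signs Stratify positive seeds over weight signs?
#' @return Seed data frame (`gene_m`, `gene_n`, `delay`, `label`).
#' @export
make_seed_labels <- function(truth, genes, n_pos = 2, n_neg = 2, seed = 1L,
                             neg_pool = c("non_edge", "unrelated"),
                             balance_signs = FALSE) {
  neg_pool <- match.arg(neg_pool)
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  if (n_pos < 1L) stop("n_pos must be >= 1 (propagation needs the +1 class)")
  if (n_neg < 1L) stop("n_neg must be >= 1 (propagation needs the -1 class)")
  if (nrow(truth) < n_pos) stop("not enough true edges for n_pos = ", n_pos)
  tk <- paste(pmin(truth$regulator, truth$target),
              pmax(truth$regulator, truth$target), sep = "\r")
  cmb <- utils::combn(length(genes), 2L)
  negs <- data.frame(gene_m = genes[cmb[1L, ]], gene_n = genes[cmb[2L, ]],
                     stringsAsFactors = FALSE)
  nk <- paste(pmin(negs$gene_m, negs$gene_n),
              pmax(negs$gene_m, negs$gene_n), sep = "\r")
  negs <- negs[!(nk %in% tk), , drop = FALSE]
  if (nrow(negs) < n_neg)
    stop("not enough negative candidate pairs (", nrow(negs),
         ") for n_neg = ", n_neg)
  set.seed(as.integer(seed))
  resample <- function(x, k) x[sample.int(length(x), k)]
  if (balance_signs && n_pos >= 2L &&
      any(truth$decision_value > 0) && any(truth$decision_value < 0)) {
    up <- which(truth$decision_value > 0)
    dn <- which(truth$decision_value < 0)
    n_up <- min(length(up), ceiling(n_pos / 2))
    n_dn <- min(length(dn), n_pos - n_up)
    pos_idx <- c(resample(up, n_up), resample(dn, n_dn))
    rest <- setdiff(seq_len(nrow(truth)), pos_idx)
    if (length(pos_idx) < n_pos)
      pos_idx <- c(pos_idx, resample(rest, n_pos - length(pos_idx)))
  } else {
    pos_idx <- sample.int(nrow(truth), n_pos)
  }
  if (neg_pool == "unrelated") {
    unk <- with(unrelated_pairs(truth, genes),
                paste(pmin(gene_m, gene_n), pmax(gene_m, gene_n), sep = "\r"))
    negk <- paste(pmin(negs$gene_m, negs$gene_n),
                  pmax(negs$gene_m, negs$gene_n), sep = "\r")
    pref <- which(negk %in% unk)
    rest <- which(!(negk %in% unk))
    neg_idx <- if (length(pref) >= n_neg) resample(pref, n_neg)
               else c(pref, resample(rest, n_neg - length(pref)))
  } else {
    neg_idx <- sample.int(nrow(negs), n_neg)
  }
  rbind(
    data.frame(gene_m = truth$regulator[pos_idx],
               gene_n = truth$target[pos_idx],
               delay = truth$delay[pos_idx], label = 1L,
               stringsAsFactors = FALSE),
    data.frame(gene_m = negs$gene_m[neg_idx], gene_n = negs$gene_n[neg_idx],
               delay = 0L, label = -1L, stringsAsFactors = FALSE))
}
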