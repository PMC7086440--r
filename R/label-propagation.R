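#' Build the k-nearest-neighbour similarity graph over (pair, delay) samples
#'
#' Pairwise Euclidean distances are computed on the standardized feature
#' triples, converted to Gaussian (RBF) kernel similarities
#' `w = exp(-d^2 / (2 sigma^2))`, and sparsified to each sample's `k_neighbors`
#' nearest samples. The stored graph is the symmetric union: samples i and j
#' are connected when either lists the other among its nearest neighbours.
#' Self-similarity is 0. With `sigma = "auto"` the bandwidth is the standard
#' deviation of all pairwise distances, a single scale-aware default.
#'
#' @param features A `delay_features` table from [assemble_features()].
#' @param k_neighbors Number of nearest neighbours per sample (ties broken by
#'   canonical row order).
#' @param sigma Kernel bandwidth (> 0), or `"auto"`.
#' @return An object of class `sample_graph`: list with `W` (symmetric
#'   similarity matrix, zero off the neighbour union), `knn` (logical matrix
#'   of directed nearest-neighbour lists), `sigma`, `k_neighbors`,
#'   `n_samples`.
#' @export
build_graph <- function(features, k_neighbors = 7, sigma = "auto") {
  X <- attr(features, "scaled")
  if (is.null(X)) stop("features must come from assemble_features()")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (n < k_neighbors + 1L)
    stop("need at least k_neighbors + 1 samples (got ", n, ")")
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  if (identical(sigma, "auto")) sigma <- stats::sd(D[upper.tri(D)])
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive number (or \"auto\")")
  K <- exp(-D^2 / (2 * sigma^2))
  diag(K) <- 0
  k <- min(k_neighbors, n - 1L)
  knn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- seq_len(n)[-i]
    nb <- cand[order(D[i, cand], cand)][seq_len(k)]
    knn[i, nb] <- TRUE
  }
  adj <- knn | t(knn)
  W <- K * adj
  structure(list(W = W, knn = knn, sigma = sigma, k_neighbors = k,
                 n_samples = n),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("sample_graph: %d samples, k = %d, sigma = %.4g, %d edges\n",
              x$n_samples, x$k_neighbors, x$sigma, sum(x$W > 0) / 2))
  invisible(x)
}

#' Propagate fuzzy class labels over the sample graph
#'
#' Semisupervised two-class (regulation / no regulation) fuzzy label
#' propagation. Seed samples are clamped to one-hot membership vectors
#' ((1,0) for label +1, (0,1) for label -1); every other sample starts at
#' (0.5, 0.5) and is synchronously replaced by the similarity-weighted
#' average of its neighbours' membership vectors until the largest absolute
#' membership change drops below `tol` or `max_iter` sweeps have run. Rows
#' stay on the probability simplex throughout, and the fixed point is the
#' harmonic extension of the clamped seed labels over the graph.
#'
#' @param graph A `sample_graph` from [build_graph()].
#' @param seeds Data frame with columns `sample` (row index into the feature
#'   table) and `label` (+1 or -1); both classes must be present.
#' @param tol Convergence tolerance on the membership change.
#' @param max_iter Maximum number of synchronous sweeps.
#' @return An object of class `fuzzy_labels`: list with `membership`
#'   (n x 2 matrix, column 1 = regulation), `clamped` (logical), `decision`
#'   (membership difference, column 1 minus column 2), `iterations`,
#'   `converged`.
#' @export
propagate <- function(graph, seeds, tol = 1e-6, max_iter = 1000) {
  if (!inherits(graph, "sample_graph")) stop("graph must come from build_graph()")
  n <- graph$n_samples
  seeds <- as.data.frame(seeds)
  if (!all(c("sample", "label") %in% names(seeds)))
    stop("seeds must have columns 'sample' and 'label'")
  idx <- as.integer(seeds$sample)
  lab <- as.integer(seeds$label)
  if (any(idx < 1L | idx > n)) stop("seed sample index out of range")
  if (anyDuplicated(idx)) stop("duplicate seed sample")
  if (!all(lab %in% c(1L, -1L))) stop("seed labels must be +1 or -1")
  if (!any(lab == 1L) || !any(lab == -1L))
    stop("seeds must contain at least one sample of each class")
  FF <- matrix(0.5, n, 2L)
  FF[idx, ] <- cbind(as.numeric(lab == 1L), as.numeric(lab == -1L))
  clamped <- rep(FALSE, n)
  clamped[idx] <- TRUE
  W <- graph$W
  rs <- rowSums(W)
  dead <- !clamped & rs == 0
  if (any(dead))
    stop("unlabeled sample(s) with zero total neighbour similarity: ",
         paste(which(dead), collapse = ", "))
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    Fnew <- sweep(W %*% FF, 1L, rs, "/")
    Fnew[clamped, ] <- FF[clamped, ]
    delta <- max(abs(Fnew - FF))
    FF <- Fnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("label propagation did not converge in ", max_iter, " iterations")
  structure(list(membership = FF, clamped = clamped,
                 decision = FF[, 1L] - FF[, 2L],
                 iterations = it, converged = converged),
            class = "fuzzy_labels")
}

#' @export
print.fuzzy_labels <- function(x, ...) {
  cat(sprintf(
    "fuzzy_labels: %d samples (%d seeds), %d iterations, %sconverged\n",
    nrow(x$membership), sum(x$clamped), x$iterations,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Decode regulation edges and their delays from converged memberships
#'
#' The scalar decision value of a sample is its regulation membership minus
#' its no-regulation membership. Non-positive decisions are zeroed; then, for
#' each unordered gene pair, the delay (across both orientations) with the
#' maximal surviving decision value becomes the pair's single edge. Direction
#' follows the lead convention of the feature table — in a record (m, n, a)
#' gene n is the delayed series, so the decoded edge is m -> n. Ties on the
#' maximum go to the smallest delay, then to the orientation in which the
#' regulator precedes the target in input gene order (at delay 0 the two
#' orientations carry identical features, so a delay-0 edge is effectively
#' undirected and reported in canonical input order). Pairs whose every delay
#' was zeroed yield no edge; self-pairs are never emitted.
#'
#' @param state A converged `fuzzy_labels` object over the same samples.
#' @param features The `delay_features` table the graph was built from.
#' @return Edge data frame with columns `regulator`, `target`, `delay`,
#'   `decision_value`, one row per recovered gene pair.
#' @export
decide_edges <- function(state, features) {
  if (!inherits(state, "fuzzy_labels")) stop("state must come from propagate()")
  if (nrow(features) != nrow(state$membership))
    stop("state and features describe different sample sets")
  d <- state$decision
  d[d <= 0] <- 0
  genes <- attr(features, "gene_ids")
  im <- match(features$gene_m, genes)
  in_ <- match(features$gene_n, genes)
  keep <- im != in_
  key <- paste(pmin(im, in_), pmax(im, in_), sep = "_")
  out <- list()
  for (k in unique(key[keep])) {
    rows <- which(keep & key == k)
    if (all(d[rows] == 0)) next
    ord <- rows[order(-d[rows], features$delay[rows],
                      as.integer(im[rows] > in_[rows]))]
    r <- ord[1L]
    out[[length(out) + 1L]] <- data.frame(
      regulator = features$gene_m[r], target = features$gene_n[r],
      delay = features$delay[r], decision_value = d[r],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(regulator = character(0), target = character(0),
                      delay = integer(0), decision_value = numeric(0),
                      stringsAsFactors = FALSE))
  edges <- do.call(rbind, out)
  ri <- match(edges$regulator, genes)
  ti <- match(edges$target, genes)
  edges <- edges[order(pmin(ri, ti), pmax(ri, ti)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
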