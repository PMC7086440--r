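#' Discretize expression profiles into per-step trends
#'
#' Each consecutive pair of time points is reduced to its direction of
#' change: +1 rising, 0 flat, -1 falling. The resulting N x (P-1) sign
#' matrix is the basis of the relative change trend score.
#'
#' @param x An [expr_ts] object or fully observed numeric matrix.
#' @return Integer matrix with entries in \{-1, 0, 1\} and P-1 columns.
#' @export
#' @examples
#' discretize_trend(rbind(a = c(1, 2, 2, 1.5), b = c(0, 1, 2, 3)))
discretize_trend <- function(x) {
  V <- if (inherits(x, "expr_ts")) x$values else as.matrix(x)
  if (anyNA(V)) stop("expression matrix must be fully observed (impute first)")
  if (ncol(V) < 2L) stop("need at least 2 time points")
  b <- sign(V[, -1L, drop = FALSE] - V[, -ncol(V), drop = FALSE])
  storage.mode(b) <- "integer"
  dimnames(b) <- NULL
  b
}

#' Relative change trend score of a lagged gene pair
#'
#' Measures how consistently the up/down/flat trend pattern of gene `m`
#' co-moves with the trend pattern of gene `n` after `n` is delayed by `a`
#' sampling intervals. Step signs are multiplied pairwise
#' (`b'_j = b_mj * b_{n,j+a}`), consecutive products are multiplied again
#' (`s_j = b'_j * b'_{j+1}`), and the score is the fraction of `s_j` equal to
#' 1 out of the `P - 2 - a` comparisons. A consistently opposite trend scores
#' just as high as a consistently parallel one, so repression is treated like
#' activation.
#'
#' @param b Trend matrix from [discretize_trend()].
#' @param m,n Gene row indices.
#' @param a Delay in sampling intervals, `0 <= a <= P - 3`.
#' @return Score in \[0, 1\].
#' @export
trend_score <- function(b, m, n, a) {
  P <- ncol(b) + 1L
  if (a < 0L || a > P - 3L)
    stop("delay a must satisfy 0 <= a <= P - 3 (got a = ", a, ", P = ", P, ")")
  j <- seq_len(P - 1L - a)
  bp <- b[m, j] * b[n, j + a]
  s <- bp[-length(bp)] * bp[-1L]
  sum(s == 1) / (P - 2L - a)
}

#' Lagged Pearson correlation of a gene pair
#'
#' Correlates the first `P - a` values of gene `m` with the last `P - a`
#' values of gene `n` (i.e. `n` delayed by `a` intervals), using the means of
#' the truncated segments. If either segment has zero variance the
#' correlation is defined as 0 so the feature table stays total. The result
#' is clamped to \[-1, 1\] against rounding.
#'
#' @inheritParams trend_score
#' @param x An [expr_ts] object or fully observed numeric matrix.
#' @return Correlation in \[-1, 1\].
#' @export
delay_correlation <- function(x, m, n, a) {
  V <- if (inherits(x, "expr_ts")) x$values else as.matrix(x)
  if (anyNA(V)) stop("expression matrix must be fully observed (impute first)")
  P <- ncol(V)
  if (a < 0L || P - a < 3L)
    stop("delay a must satisfy P - a >= 3 (got a = ", a, ", P = ", P, ")")
  xm <- V[m, seq_len(P - a)]
  xn <- V[n, seq.int(1L + a, P)]
  dm <- xm - mean(xm)
  dn <- xn - mean(xn)
  den <- sqrt(sum(dm^2) * sum(dn^2))
  if (den == 0) return(0)
  max(-1, min(1, sum(dm * dn) / den))
}

# Equal-width bin labels for a segment, with edges spanning the gene's
# full-series range. Zero range puts all mass in bin 1.
bin_segment <- function(full_series, segment, bins) {
  rng <- range(full_series)
  if (rng[1L] == rng[2L]) return(rep(1L, length(segment)))
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  findInterval(segment, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

plugin_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Delayed mutual information of a gene pair
#'
#' Plug-in mutual information, in bits, between the binned first `P - a`
#' values of gene `m` and the binned last `P - a` values of gene `n`. Each
#' gene is discretized into `bins` equal-width intervals spanning that gene's
#' full-series range (so the same bin edges apply at every delay); marginal
#' and joint probabilities are relative frequencies over the aligned
#' segments, and `M = H_m + H_n - H_mn`. A zero-range segment carries zero
#' entropy and contributes zero information. The result is clamped at 0
#' against rounding.
#'
#' @inheritParams delay_correlation
#' @param bins Number of equal-width bins per gene (>= 2).
#' @return Mutual information in bits, >= 0.
#' @export
delay_mutual_information <- function(x, m, n, a, bins = 3) {
  V <- if (inherits(x, "expr_ts")) x$values else as.matrix(x)
  if (anyNA(V)) stop("expression matrix must be fully observed (impute first)")
  P <- ncol(V)
  if (a < 0L || P - a < 2L) stop("delay a must satisfy P - a >= 2")
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  bm <- bin_segment(V[m, ], V[m, seq_len(P - a)], bins)
  bn <- bin_segment(V[n, ], V[n, seq.int(1L + a, P)], bins)
  joint <- table(factor(bm, levels = seq_len(bins)),
                 factor(bn, levels = seq_len(bins)))
  pj <- joint / sum(joint)
  Hm <- plugin_entropy(rowSums(pj))
  Hn <- plugin_entropy(colSums(pj))
  Hmn <- plugin_entropy(as.vector(pj))
  max(0, Hm + Hn - Hmn)
}

#' Assemble the per-(pair, delay) similarity feature table
#'
#' Flattens the gene-pair similarity evaluation tensor into one record per
#' ordered gene pair and delay, in pair-major / delay-minor order: (gene 1,
#' gene 1, a = 0), (gene 1, gene 1, a = 1), ..., (gene N, gene N, a = A).
#' Each record carries the three raw similarity features; a z-score
#' standardized copy of each feature column (used for all downstream distance
#' computations, so the mixed scales of the three measures do not dominate
#' one another) is attached as the `"scaled"` attribute. Self-pairs are kept
#' by default — they can anchor label propagation — but are never decoded
#' into edges.
#'
#' @param x An [expr_ts] object (fully observed) or numeric matrix.
#' @param max_delay Maximum delay A, in sampling intervals; `A <= P - 3`.
#' @param bins Bin count for the mutual-information feature.
#' @param include_self Keep records pairing a gene with itself?
#' @return A data frame of class `delay_features` with columns `gene_m`,
#'   `gene_n`, `delay`, `trend_score`, `correlation`, `mutual_information`,
#'   and attributes `scaled` (standardized feature matrix), `gene_ids`,
#'   `max_delay`, `include_self`.
#' @export
assemble_features <- function(x, max_delay, bins = 3, include_self = TRUE) {
  x <- as_expr_ts(x)
  if (!all(x$observed)) stop("expression matrix must be fully observed (impute first)")
  V <- x$values
  N <- nrow(V)
  P <- ncol(V)
  max_delay <- as.integer(max_delay)
  if (max_delay < 0L) stop("max_delay must be >= 0")
  if (max_delay > P - 3L)
    stop("max_delay must be <= P - 3 = ", P - 3L, " (got ", max_delay, ")")
  b <- discretize_trend(x)
  mm <- nn <- aa <- integer(0)
  for (m in seq_len(N)) for (n in seq_len(N)) {
    if (!include_self && m == n) next
    mm <- c(mm, rep.int(m, max_delay + 1L))
    nn <- c(nn, rep.int(n, max_delay + 1L))
    aa <- c(aa, 0:max_delay)
  }
  ts <- cor <- mi <- numeric(length(mm))
  for (r in seq_along(mm)) {
    ts[r] <- trend_score(b, mm[r], nn[r], aa[r])
    cor[r] <- delay_correlation(x, mm[r], nn[r], aa[r])
    mi[r] <- delay_mutual_information(x, mm[r], nn[r], aa[r], bins = bins)
  }
  df <- data.frame(gene_m = x$gene_ids[mm], gene_n = x$gene_ids[nn],
                   delay = aa, trend_score = ts, correlation = cor,
                   mutual_information = mi, stringsAsFactors = FALSE)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  scaled <- cbind(trend_score = zscore(ts), correlation = zscore(cor),
                  mutual_information = zscore(mi))
  structure(df,
            scaled = scaled,
            gene_ids = x$gene_ids,
            max_delay = max_delay,
            include_self = include_self,
            bins = as.integer(bins),
            class = c("delay_features", "data.frame"))
}

# Row index of the (gene_m, gene_n, delay) sample in the canonical flattening.
feature_row <- function(features, gene_m, gene_n, delay) {
  idx <- which(features$gene_m == gene_m & features$gene_n == gene_n &
                 features$delay == delay)
  if (length(idx) != 1L)
    stop(sprintf("no sample for (%s, %s, delay %d) in the feature table",
                 gene_m, gene_n, delay))
  idx
}
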