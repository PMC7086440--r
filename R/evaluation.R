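#' Confusion counts of a predicted edge set against a reference network
#'
#' Every pair in the evaluation universe (by default all unordered non-self
#' pairs of the gene set) is classified: predicted and in the reference ->
#' TP; predicted only -> FP; in the reference only -> FN; in neither -> TN.
#' Matching is on the gene pair, undirected and delay-blind, mirroring how
#' recovered pairs are usually tabulated against literature networks whose
#' direction is not machine-readable; delay agreement among true positives
#' is reported separately and never changes the four counts. Directed
#' matching (regulator -> target must agree) is available via `directed`.
#'
#' @param pred Predicted edge data frame (`regulator`, `target`, `delay`).
#' @param truth Reference edge data frame, same columns (`decision_value`
#'   optional).
#' @param genes Character vector of all genes defining the universe.
#' @param directed Match ordered pairs instead of unordered ones.
#' @return An object of class `grn_confusion`: list with `tp`, `tn`, `fp`,
#'   `fn`, `delay_correct` (true positives whose predicted delay equals the
#'   reference delay), `n_universe`.
#' @export
edge_confusion <- function(pred, truth, genes, directed = FALSE) {
  pair_key <- function(a, b) {
    ia <- match(a, genes); ib <- match(b, genes)
    unknown <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    if (length(unknown))
      stop("edge refers to gene(s) outside the universe: ",
           paste(unknown, collapse = ", "))
    if (directed) paste(ia, ib, sep = ">")
    else paste(pmin(ia, ib), pmax(ia, ib), sep = "_")
  }
  n <- length(genes)
  if (n < 2L) stop("universe needs at least 2 genes")
  cmb <- utils::combn(n, 2L)
  universe <- if (directed) {
    c(paste(cmb[1L, ], cmb[2L, ], sep = ">"), paste(cmb[2L, ], cmb[1L, ], sep = ">"))
  } else {
    paste(cmb[1L, ], cmb[2L, ], sep = "_")
  }
  pk <- if (nrow(pred)) pair_key(pred$regulator, pred$target) else character(0)
  tk <- if (nrow(truth)) pair_key(truth$regulator, truth$target) else character(0)
  if (!all(pk %in% universe))
    stop("predicted edge outside the evaluation universe")
  in_pred <- universe %in% pk
  in_truth <- universe %in% tk
  tp_keys <- universe[in_pred & in_truth]
  delay_correct <- 0L
  for (k in tp_keys) {
    pd <- pred$delay[pk == k][1L]
    td <- truth$delay[tk == k][1L]
    if (isTRUE(pd == td)) delay_correct <- delay_correct + 1L
  }
  structure(list(tp = sum(in_pred & in_truth),
                 tn = sum(!in_pred & !in_truth),
                 fp = sum(in_pred & !in_truth),
                 fn = sum(!in_pred & in_truth),
                 delay_correct = delay_correct,
                 n_universe = length(universe)),
            class = "grn_confusion")
}

#' @export
print.grn_confusion <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d (universe %d; delays correct %d/%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$n_universe, x$delay_correct, x$tp))
  invisible(x)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / (TP + FP + TN + FN)`, all returned as percentages at
#' full precision (the print method rounds to one decimal for display).
#'
#' @param x A `grn_confusion` object, or the TP count.
#' @param tn,fp,fn Remaining counts when `x` is given as a number.
#' @return A list of class `grn_metrics` with elements `sn`, `sp`, `acc`
#'   (percent).
#' @export
#' @examples
#' grn_metrics(14, 187, 25, 18)
grn_metrics <- function(x, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(x, "grn_confusion")) {
    tp <- x$tp; tn <- x$tn; fp <- x$fp; fn <- x$fn
  } else {
    tp <- x
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all four confusion counts are zero")
  if (tp + fn == 0) stop("sensitivity undefined: TP + FN = 0")
  if (tn + fp == 0) stop("specificity undefined: TN + FP = 0")
  structure(list(sn = 100 * tp / (tp + fn),
                 sp = 100 * tn / (tn + fp),
                 acc = 100 * (tp + tn) / (tp + tn + fp + fn)),
            class = "grn_metrics")
}

#' @export
print.grn_metrics <- function(x, ...) {
  cat(sprintf("Sn %.1f%%  Sp %.1f%%  Acc %.1f%%\n", x$sn, x$sp, x$acc))
  invisible(x)
}

#' Fraction of reference pairs recovered by a prediction
#'
#' The analogue of the recovered-pair fraction reported for small literature
#' networks: how many reference gene pairs appear in the predicted edge set
#' (undirected), optionally also requiring the predicted delay to equal the
#' reference delay.
#'
#' @param pred,truth Edge data frames.
#' @param require_delay Count a pair only if its delay matches.
#' @return Fraction in \[0, 1\].
#' @export
edge_recovery <- function(pred, truth, require_delay = FALSE) {
  if (nrow(truth) == 0L) stop("reference edge set is empty")
  ukey <- function(e) paste(pmin(e$regulator, e$target),
                            pmax(e$regulator, e$target), sep = "\r")
  tk <- ukey(truth)
  if (nrow(pred) == 0L) return(0)
  pk <- ukey(pred)
  hit <- tk %in% pk
  if (require_delay) {
    for (i in which(hit)) {
      pd <- pred$delay[pk == tk[i]][1L]
      if (!isTRUE(pd == truth$delay[i])) hit[i] <- FALSE
    }
  }
  mean(hit)
}

#' One method's classification error-rate sample
#'
#' Summary of repeated classification runs of one method, treated as draws
#' from a normal distribution: the mean error rate, the (unbiased) sample
#' variance used as the variance estimate, and the number of runs.
#'
#' @param mean Mean classification error rate, a fraction in \[0, 1\].
#' @param variance Sample variance, >= 0.
#' @param n Number of runs, >= 1.
#' @return A list of class `error_rate_sample`.
#' @export
error_rate_sample <- function(mean, variance, n) {
  if (mean < 0 || mean > 1) stop("mean error rate must lie in [0, 1]")
  if (variance < 0) stop("variance must be >= 0")
  if (n < 1) stop("n must be >= 1")
  structure(list(mean = mean, variance = variance, n = as.integer(n)),
            class = "error_rate_sample")
}

#' Two-sample z comparison of classification error rates
#'
#' Tests H0: mu1 >= mu2 against H1: mu1 < mu2 with the two-sample statistic
#' `U = (mean1 - mean2) / sqrt(var1/n1 + var2/n2)`; H0 is rejected when
#' `U <= -z_alpha`, with the upper-alpha normal quantile computed at run
#' time.
#'
#' @param s1,s2 [error_rate_sample()] objects (method 1 vs method 2).
#' @param alpha Significance level in (0, 1).
#' @return List with `U`, `z_alpha`, and logical `reject`.
#' @export
#' @examples
#' compare_error_rates(error_rate_sample(0.1, 0.01, 100),
#'                     error_rate_sample(0.2, 0.01, 100))
compare_error_rates <- function(s1, s2, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  se2 <- s1$variance / s1$n + s2$variance / s2$n
  if (se2 == 0) stop("zero pooled variance: the statistic is undefined")
  U <- (s1$mean - s2$mean) / sqrt(se2)
  z <- stats::qnorm(1 - alpha)
  list(U = U, z_alpha = z, reject = U <= -z)
}
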