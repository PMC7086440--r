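#' Time-series expression matrix
#'
#' Container for a genes-by-time-points expression matrix on a log-ratio
#' scale, together with a logical mask marking which cells were actually
#' observed. This is the object every other function in the package consumes.
#'
#' @param values Numeric matrix, one row per gene, one column per time point.
#'   Row names are taken as gene identifiers; unnamed rows get `g1`, `g2`, ...
#'   Cells that are `NA` are treated as unobserved unless `observed` says
#'   otherwise.
#' @param observed Optional logical matrix of the same shape; `TRUE` marks an
#'   observed cell. Defaults to `!is.na(values)`.
#'
#' @return An object of class `expr_ts`: a list with elements `gene_ids`
#'   (character), `values` (numeric matrix) and `observed` (logical matrix).
#' @export
#' @examples
#' m <- matrix(rnorm(24), 4, 6, dimnames = list(paste0("G", 1:4), NULL))
#' x <- expr_ts(m)
#' dim(x$values)
expr_ts <- function(values, observed = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("at least 2 genes are required")
  if (ncol(values) < 4L) stop("at least 4 time points are required")
  ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty gene id")
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(values)))
    stop("'observed' must have the same shape as 'values'")
  values[!observed] <- NA_real_
  if (any(is.na(values[observed])))
    stop("non-finite value in an observed cell")
  dimnames(values) <- list(ids, colnames(values))
  dimnames(observed) <- dimnames(values)
  structure(list(gene_ids = ids, values = values, observed = observed),
            class = "expr_ts")
}

#' @export
print.expr_ts <- function(x, ...) {
  cat(sprintf("expr_ts: %d genes x %d time points (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(!x$observed)))
  invisible(x)
}

# Accept either an expr_ts or a bare matrix (coerced on the fly).
as_expr_ts <- function(x) {
  if (inherits(x, "expr_ts")) return(x)
  expr_ts(x)
}

#' Read a tab-separated expression matrix
#'
#' The expected layout is one header row of time-point labels, then one row
#' per gene with the gene identifier in the first column. Cells equal to one
#' of `missing_tokens` (case-insensitive) or empty are marked unobserved.
#'
#' @param path Path to a TSV file.
#' @param missing_tokens Character vector of tokens denoting a missing value.
#' @return An [expr_ts] object, rows in file order.
#' @export
read_expression <- function(path, missing_tokens = c("", "NA", "NaN")) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop("expression file needs a gene column plus time points")
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells_trim <- trimws(cells)
  miss <- matrix(tolower(cells_trim) %in% tolower(missing_tokens) |
                   !nzchar(cells_trim), nrow(cells), ncol(cells))
  vals <- suppressWarnings(matrix(as.numeric(cells_trim),
                                  nrow(cells), ncol(cells)))
  bad <- !miss & is.na(vals)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell for gene '%s' at time point %d: '%s'",
                 ids[w[1L]], w[2L], cells[w[1L], w[2L]]))
  }
  vals[miss] <- NA_real_
  rownames(vals) <- ids
  colnames(vals) <- colnames(raw)[-1L]
  expr_ts(vals, observed = !miss)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header row, first column `gene`,
#' unobserved cells written as `missing_token`.
#'
#' @param x An [expr_ts] object or numeric matrix.
#' @param path Output path.
#' @param missing_token Token written for unobserved cells.
#' @export
write_expression <- function(x, path, missing_token = "NA") {
  x <- as_expr_ts(x)
  tp <- colnames(x$values)
  if (is.null(tp)) tp <- paste0("t", seq_len(ncol(x$values)))
  cells <- matrix(format(x$values, digits = 15, trim = TRUE, scientific = FALSE),
                  nrow(x$values), ncol(x$values))
  cells[!x$observed] <- missing_token
  df <- data.frame(gene = x$gene_ids, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene", tp)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing expression values by k-nearest-neighbour rows
#'
#' Each missing cell (i, j) is replaced by the inverse-distance-weighted mean
#' of column-j values of the k nearest gene rows, where distance is Euclidean
#' over the columns observed in both rows. Neighbours must themselves be
#' observed at column j. Zero-distance neighbours take over with a plain mean.
#' A row with no usable neighbour for some cell falls back to its own mean of
#' observed values. Observed cells are never altered, so the operation is
#' idempotent.
#'
#' @param x An [expr_ts] object.
#' @param k Number of neighbour rows, capped at the number of genes minus one.
#' @return An [expr_ts] with an all-`TRUE` observed mask.
#' @export
impute_missing <- function(x, k = 10) {
  x <- as_expr_ts(x)
  if (all(x$observed)) return(x)
  V <- x$values
  obs <- x$observed
  n <- nrow(V)
  k <- max(1L, min(as.integer(k), n - 1L))
  none <- rowSums(obs) == 0L
  if (any(none))
    stop("gene(s) with no observed values: ",
         paste(x$gene_ids[none], collapse = ", "))
  filled <- V
  for (i in which(rowSums(!obs) > 0L)) {
    d <- rep(NA_real_, n)
    for (r in seq_len(n)[-i]) {
      shared <- obs[i, ] & obs[r, ]
      if (any(shared))
        d[r] <- sqrt(sum((V[i, shared] - V[r, shared])^2))
    }
    for (j in which(!obs[i, ])) {
      cand <- which(!is.na(d) & obs[, j])
      if (length(cand) == 0L) {
        filled[i, j] <- mean(V[i, obs[i, ]])
        next
      }
      nb <- cand[order(d[cand], cand)]
      nb <- nb[seq_len(min(k, length(nb)))]
      if (any(d[nb] == 0)) {
        filled[i, j] <- mean(V[nb[d[nb] == 0], j])
      } else {
        w <- 1 / d[nb]
        filled[i, j] <- sum(w * V[nb, j]) / sum(w)
      }
    }
  }
  expr_ts(filled)
}

#' Read seed-labelled gene pairs
#'
#' Seed labels anchor the semisupervised classification: `+1` marks a pair
#' (at a stated delay) known to be a regulation, `-1` a pair known not to be.
#' File columns (tab-separated, header required): `gene_m`, `gene_n`,
#' `delay`, `label`.
#'
#' @param path Path to the TSV file.
#' @param genes Optional character vector of valid gene ids; if supplied,
#'   any seed naming an unknown gene is an error.
#' @return A data frame with columns `gene_m`, `gene_n`, `delay`, `label`.
#' @export
read_seed_labels <- function(path, genes = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_m", "gene_n", "delay", "label")
  if (!all(need %in% names(df)))
    stop("seed file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$delay <- as.integer(df$delay)
  df$label <- as.integer(df$label)
  if (any(is.na(df$delay)) || any(df$delay < 0L))
    stop("delay must be a non-negative integer")
  if (!all(df$label %in% c(1L, -1L)))
    stop("label must be 1 or -1")
  if (!is.null(genes)) {
    unknown <- setdiff(unique(c(df$gene_m, df$gene_n)), genes)
    if (length(unknown))
      stop("seed refers to unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  df
}

#' Write seed labels
#' @param seeds Data frame with columns `gene_m`, `gene_n`, `delay`, `label`.
#' @param path Output path.
#' @export
write_seed_labels <- function(seeds, path) {
  utils::write.table(seeds[, c("gene_m", "gene_n", "delay", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a decoded edge set
#'
#' Edges are tab-separated with header `regulator`, `target`, `delay`,
#' `decision_value`. The delay is in whole time-sampling intervals; the
#' decision value is the fuzzy membership margin (regulation minus
#' no-regulation) that survived thresholding, or any score for an externally
#' supplied reference network (it may be omitted in a truth file).
#'
#' @param edges Data frame with the four edge columns (`decision_value`
#'   optional on read).
#' @param path File path.
#' @return `read_edges` returns a data frame with the four columns
#'   (`decision_value` filled with `NA` when absent).
#' @export
write_edges <- function(edges, path) {
  df <- as.data.frame(edges)[, c("regulator", "target", "delay",
                                 "decision_value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("regulator", "target", "delay")
  if (!all(need %in% names(df)))
    stop("edge file must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$decision_value)) df$decision_value <- NA_real_
  df <- df[, c(need, "decision_value")]
  df$delay <- as.integer(df$delay)
  if (any(df$regulator == df$target)) stop("self-edge in edge file")
  df
}

#' Export an edge set in SIF format for network viewers
#'
#' One line per edge: `regulator  regulates-delay-<a>  target`.
#'
#' @param edges Edge data frame.
#' @param path Output path.
#' @export
write_sif <- function(edges, path) {
  lines <- sprintf("%s\tregulates-delay-%d\t%s",
                   edges$regulator, edges$delay, edges$target)
  writeLines(lines, path)
  invisible(path)
}
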