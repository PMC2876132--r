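#' Median-center an expression matrix
#'
#' @param X An [expression_matrix()].
#' @param mode `"per_gene"` subtracts each gene's median across samples
#'   (default; the model compares patterns across samples within genes);
#'   `"per_dataset"` subtracts the single global median.
#' @return A centered [expression_matrix()].
#' @export
median_center <- function(X, mode = c("per_gene", "per_dataset")) {
  mode <- match.arg(mode)
  X <- as_expression_matrix(X)
  v <- unclass(X)
  v <- if (mode == "per_gene") {
    v - apply(v, 1, median)
  } else {
    v - median(v)
  }
  expression_matrix(v, rownames(X), colnames(X))
}

#' COPA variation scores
#'
#' Cancer-outlier-profile-style gene variation filter: each gene is
#' median-centered, scaled by its MAD (with the 1.4826 normal-consistency
#' constant), and scored by an upper percentile of the transformed values.
#' Genes with outlier expression in a subset of samples score high even when
#' their overall variance is modest.  Genes with zero MAD get score 0 with a
#' warning.
#'
#' @param X An [expression_matrix()].
#' @param percentile Percentile in (50, 100); default 95.
#' @return Object of class `"copa_scores"`: list with `score` (named numeric
#'   per gene) and `percentile`.
#' @export
copa_scores <- function(X, percentile = 95) {
  if (percentile <= 50 || percentile >= 100)
    stop("percentile must lie in (50, 100)")
  X <- as_expression_matrix(X)
  med <- apply(X, 1, median)
  madv <- apply(X, 1, mad)              # constant = 1.4826
  zero <- madv == 0
  if (any(zero))
    warning(sum(zero), " gene(s) with zero MAD scored 0")
  score <- numeric(nrow(X))
  names(score) <- rownames(X)
  if (any(!zero)) {
    z <- (unclass(X)[!zero, , drop = FALSE] - med[!zero]) / madv[!zero]
    score[!zero] <- apply(z, 1, quantile, probs = percentile / 100,
                          names = FALSE)
  }
  structure(list(score = score, percentile = percentile),
            class = "copa_scores")
}

#' Keep the top-k genes by COPA score
#'
#' @param X An [expression_matrix()].
#' @param scores A [copa_scores()] object for the same genes.
#' @param k Number of genes to keep (`k <= N`).
#' @return An [expression_matrix()] with the `k` highest-scoring rows, in
#'   their original order; ties are broken by input order.
#' @export
filter_top_genes <- function(X, scores, k) {
  X <- as_expression_matrix(X)
  s <- scores$score
  if (length(s) != nrow(X)) stop("scores do not match the matrix rows")
  if (k < 1L || k > nrow(X)) stop("k must be between 1 and the gene count")
  keep <- sort(order(s, decreasing = TRUE)[seq_len(k)])  # order() is stable
  out <- unclass(X)[keep, , drop = FALSE]
  rownames(out) <- rownames(X)[keep]
  # k = 1 is a legitimate filter result even though the model itself needs
  # at least 2 genes, so skip the constructor's size check
  class(out) <- c("expression_matrix", class(out))
  out
}
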