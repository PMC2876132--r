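#' Posterior pairwise co-grouping probabilities from chain counts
#'
#' The PPP between two items (genes or samples) is the proportion of kept
#' Gibbs sweeps in which they were grouped together; it is the similarity
#' measure used for all dendrograms in this package.
#'
#' @param counts Symmetric integer count matrix with diagonal equal to
#'   `n_kept` (as produced by [run_chain()]).
#' @param n_kept Number of kept sweeps the counts were accumulated over.
#' @return An object of class `"ppp_matrix"`: list with `values` (symmetric,
#'   unit diagonal, entries in \[0, 1\]), `item_ids`, `n_kept`.
#' @export
ppp_from_counts <- function(counts, n_kept) {
  if (n_kept <= 0) stop("n_kept must be positive")
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || !isTRUE(all.equal(counts, t(counts))))
    stop("counts must be a symmetric matrix")
  if (any(counts < 0) || any(counts > n_kept))
    stop("counts must lie in [0, n_kept]")
  if (any(diag(counts) != n_kept))
    stop("count diagonal must equal n_kept")
  structure(list(values = counts / n_kept,
                 item_ids = rownames(counts) %||%
                   paste0("item_", seq_len(nrow(counts))),
                 n_kept = n_kept),
            class = "ppp_matrix")
}

as_ppp_matrix <- function(x) {
  if (inherits(x, "ppp_matrix")) return(x)
  x <- as.matrix(x)
  if (any(x < 0) || any(x > 1) || any(abs(diag(x) - 1) > 1e-12))
    stop("a PPP matrix must have entries in [0,1] and unit diagonal")
  structure(list(values = x,
                 item_ids = rownames(x) %||% paste0("item_", seq_len(nrow(x))),
                 n_kept = NA_integer_),
            class = "ppp_matrix")
}

#' @export
print.ppp_matrix <- function(x, ...) {
  cat(sprintf("ppp_matrix: %d items (n_kept = %s)\n", nrow(x$values),
              x$n_kept))
  invisible(x)
}

#' Average-linkage dendrogram on PPP similarity
#'
#' Agglomerative clustering of the items of a PPP matrix with unweighted
#' average linkage on the distance `1 - PPP`.  Merge heights are average
#' inter-group distances, so cutting the tree at height `1 - p` yields
#' clusters whose average internal PPP exceeds `p`.
#'
#' @param ppp A `"ppp_matrix"` (or a plain symmetric similarity matrix with
#'   unit diagonal).
#' @return An [stats::hclust] tree, additionally of class `"merge_tree"`.
#' @export
average_linkage <- function(ppp) {
  ppp <- as_ppp_matrix(ppp)
  n <- nrow(ppp$values)
  if (n < 2L) stop("need at least 2 items to build a tree")
  d <- as.dist(1 - ppp$values)
  attr(d, "Labels") <- ppp$item_ids
  tree <- hclust(d, method = "average")
  # clamp tiny negative roundoff so heights stay in [0, 1]
  tree$height <- pmin(pmax(tree$height, 0), 1)
  class(tree) <- c("merge_tree", class(tree))
  tree
}

#' All distinct cut levels of a dendrogram
#'
#' Returns one partition per distinct merge height, cutting just below each
#' height (so tied merges stay together), plus the all-singleton partition.
#' With no tied heights this is exactly one partition per cluster count
#' `k = 1..n`.
#'
#' @param tree A tree from [average_linkage()] (any `hclust` works).
#' @return A list of integer label vectors, ordered from most to least
#'   clusters; each has contiguous labels starting at 1.
#' @export
cut_all_levels <- function(tree) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust/merge_tree")
  n <- length(tree$order)
  hs <- sort(unique(tree$height))
  parts <- vector("list", length(hs) + 1L)
  parts[[1L]] <- seq_len(n)                     # all singletons
  for (k in seq_along(hs))
    parts[[k + 1L]] <- relabel_contiguous(cutree(tree, h = hs[k]))
  names(parts) <- vapply(parts, function(p) as.character(max(p)), "")
  parts
}

relabel_contiguous <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Extract sample contexts from the sample PPP tree
#'
#' Cuts the sample dendrogram into `k` groups; these are the discovered
#' contexts, i.e. groups of samples sharing a local gene co-clustering
#' structure.
#'
#' @param sample_tree Tree built on the sample PPP matrix.
#' @param k Number of contexts (default 2, the top-level split).
#' @return Integer vector of contiguous context labels, named by sample.
#' @export
extract_contexts <- function(sample_tree, k = 2L) {
  if (!inherits(sample_tree, "hclust"))
    stop("sample_tree must be an hclust/merge_tree")
  n <- length(sample_tree$order)
  if (k < 1L || k > n) stop("k must be between 1 and the number of samples")
  labs <- relabel_contiguous(cutree(sample_tree, k = k))
  names(labs) <- sample_tree$labels
  labs
}
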