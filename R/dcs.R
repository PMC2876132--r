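#' Context-local gene co-clustering probabilities
#'
#' Runs a fixed-context chain in which samples stay in the supplied two
#' contexts while genes and local clusters are resampled, and returns, for
#' each context, the matrix of posterior probabilities that two genes share a
#' local cluster there.  These local PPPs are the input of the differential
#' co-expression score.
#'
#' @param X An [expression_matrix()].
#' @param contexts Integer vector of context labels (1 and 2), one per
#'   sample, e.g. from [extract_contexts()]; each context needs at least 2
#'   samples.
#' @param config A [chain_config()]; its `fixed_contexts` field is set from
#'   `contexts`.
#' @param prior,conc Model prior settings, as in [run_chain()].
#' @return List of two `"ppp_matrix"` objects (one per context), with the
#'   underlying `"chain_summary"` attached as attribute `"chain"`.
#' @export
local_ppp_per_context <- function(X, contexts, config = chain_config(),
                                  prior = conjugate_prior(X),
                                  conc = concentrations()) {
  X <- as_expression_matrix(X)
  contexts <- as.integer(contexts)
  if (length(contexts) != ncol(X))
    stop("contexts must have one label per sample")
  labs <- sort(unique(contexts))
  if (!identical(labs, seq_along(labs)))
    stop("context labels must be contiguous 1..R")
  if (length(labs) != 2L)
    stop("the differential co-expression score compares exactly 2 contexts")
  if (any(table(contexts) < 2L))
    stop("every context needs at least 2 samples")
  config$fixed_contexts <- contexts
  config$track_local <- "context"
  fit <- run_chain(X, config, prior, conc)
  ppps <- lapply(fit$co_local_counts, ppp_from_counts, n_kept = fit$n_kept)
  attr(ppps, "chain") <- fit
  ppps
}

#' Absolute difference of two local PPP matrices
#'
#' @param p1,p2 `"ppp_matrix"` objects over the same genes in the same order.
#' @return Symmetric matrix of elementwise `|p1 - p2|` with zero diagonal.
#' @export
diff_matrix <- function(p1, p2) {
  p1 <- as_ppp_matrix(p1); p2 <- as_ppp_matrix(p2)
  if (!identical(dim(p1$values), dim(p2$values)))
    stop("PPP matrices must have identical dimensions")
  if (!identical(p1$item_ids, p2$item_ids))
    stop("PPP matrices must cover the same genes in the same order")
  abs(p1$values - p2$values)
}

#' Cluster-level differential co-expression score of one gene
#'
#' For gene `i` inside cluster `g`, the average absolute local-PPP difference
#' between `i` and the other members of `g`:
#' `sum_{j in g, j != i} d_ij / (|g| - 1)`.  Genes outside `g`, and singleton
#' clusters, score 0.
#'
#' @param i Gene index.
#' @param g Integer vector of gene indices forming the cluster.
#' @param diff Difference matrix from [diff_matrix()].
#' @return Scalar score in \[0, 1\].
#' @export
dcs_for_cluster <- function(i, g, diff) {
  if (!(i %in% g) || length(g) < 2L) return(0)
  others <- setdiff(g, i)
  sum(diff[i, others]) / (length(g) - 1L)
}

#' Per-gene differential co-expression scores
#'
#' Builds the average-linkage tree of each context's local PPP matrix,
#' enumerates the gene clusters induced by all tree-cut levels of both trees,
#' and scores every gene by the maximum, over all those clusters, of its
#' average absolute local-PPP difference to its cluster co-members.  Genes
#' whose co-clustering partners change between the two contexts score high.
#'
#' @param p1,p2 Local `"ppp_matrix"` objects for contexts 1 and 2 (same genes,
#'   same order), e.g. from [local_ppp_per_context()].
#' @return A `data.frame` of class `"dcs_result"` with one row per gene:
#'   `gene_id`, `score` (in \[0, 1\]), `context` (the maximizing context, 1
#'   or 2), `cluster_size`, `rank` (1 = highest score), and a list-column
#'   `cluster` with the maximizing cluster's member indices.
#' @export
dcs_genes <- function(p1, p2) {
  p1 <- as_ppp_matrix(p1); p2 <- as_ppp_matrix(p2)
  d <- diff_matrix(p1, p2)
  n <- nrow(d)
  best <- numeric(n)
  best_ctx <- integer(n)
  best_cluster <- vector("list", n)
  for (i in seq_len(n)) best_cluster[[i]] <- i
  best_ctx[] <- 1L
  for (ctx in 1:2) {
    tree <- average_linkage(if (ctx == 1) p1 else p2)
    for (part in cut_all_levels(tree)) {
      for (lab in unique(part)) {
        g <- which(part == lab)
        if (length(g) < 2L) next
        # mean difference of each member to the rest of the cluster
        sc <- (colSums(d[g, g, drop = FALSE])) / (length(g) - 1L)
        upd <- sc > best[g]
        if (any(upd)) {
          ig <- g[upd]
          best[ig] <- sc[upd]
          best_ctx[ig] <- ctx
          for (ii in ig) best_cluster[[ii]] <- g
        }
      }
    }
  }
  res <- data.frame(gene_id = p1$item_ids, score = best,
                    context = best_ctx,
                    cluster_size = vapply(best_cluster, length, 1L),
                    rank = rank(-best, ties.method = "first"),
                    stringsAsFactors = FALSE)
  res$cluster <- best_cluster
  class(res) <- c("dcs_result", class(res))
  res
}

#' Significance of the overlap of two gene lists
#'
#' Summarizes a 2x2 membership table (in list A vs not, in list B vs not,
#' over a finite gene universe) by its log odds ratio (with a Haldane 0.5
#' continuity correction when any cell is zero) and the hypergeometric upper
#' tail probability of observing at least the observed overlap.
#'
#' @param listA,listB Character (or integer) vectors of gene identifiers.
#' @param universe Size of the gene universe both lists were drawn from.
#' @return List with `log_odds`, `p`, and the observed `overlap`.
#' @export
overlap_significance <- function(listA, listB, universe) {
  listA <- unique(listA); listB <- unique(listB)
  nA <- length(listA); nB <- length(listB)
  n11 <- length(intersect(listA, listB))
  n_union <- nA + nB - n11
  if (universe < n_union)
    stop("universe is smaller than the union of the two lists")
  n12 <- nA - n11
  n21 <- nB - n11
  n22 <- universe - n_union
  cells <- c(n11, n12, n21, n22)
  if (any(cells == 0)) cells <- cells + 0.5
  log_odds <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  p <- phyper(n11 - 1L, nA, universe - nA, nB, lower.tail = FALSE)
  list(log_odds = log_odds, p = p, overlap = n11)
}
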