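#' Specification of a simulated differential co-expression study
#'
#' The synthetic design plants 4 gene clusters (20, 20, 80 and 80 genes) and
#' 3 contexts of 5 samples each (N = 200 genes, M = 15 samples).  Cluster 3
#' has mean 0 and cluster 4 mean 1 in every sample; cluster 1 has mean 1 in
#' samples 1-5 only and cluster 2 mean 1 in samples 6-10 only, so only
#' clusters 1 and 2 are informative about the three contexts.  Gaussian noise
#' with standard deviation `sigma` is added everywhere.  Scenario `"D"`
#' keeps the same co-clustering structure but flips the mean from 1 to -1 in
#' samples 1-2, 6-8 and 11-12, defeating expression-level similarity while
#' leaving the contexts intact.
#'
#' @param scenario `"A"` (plain) or `"D"` (sign-flipped means).
#' @param sigma Noise standard deviation, typically in \[0.4, 0.8\].
#' @param reps Number of replicate datasets.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(scenario = c("A", "D"), sigma = 0.5,
                            reps = 100L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (sigma <= 0) stop("sigma must be positive")
  if (reps < 1L) stop("reps must be >= 1")
  structure(list(scenario = scenario, sigma = sigma,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "simulation_spec")
}

sim_mean_matrix <- function(scenario) {
  cl <- planted_gene_clusters()
  mu <- matrix(0, 200, 15)
  mu[cl == 1, 1:5] <- 1
  mu[cl == 2, 6:10] <- 1
  mu[cl == 4, ] <- 1
  if (scenario == "D") {
    flip <- c(1:2, 6:8, 11:12)
    mu[, flip] <- -mu[, flip]
  }
  mu
}

#' Planted truth of the simulation design
#'
#' @return `planted_gene_clusters()`: integer vector of length 200 with the
#'   4 planted gene-cluster labels (sizes 20, 20, 80, 80).
#'   `planted_contexts()`: integer vector of length 15 with the 3 planted
#'   context labels (5 samples each).
#' @export
planted_gene_clusters <- function() {
  rep(1:4, times = c(20L, 20L, 80L, 80L))
}

#' @rdname planted_gene_clusters
#' @export
planted_contexts <- function() {
  rep(1:3, each = 5L)
}

#' Generate one replicate of the simulation design
#'
#' @param spec A [simulation_spec()].
#' @param rep_index Replicate number (1-based); the replicate seed is
#'   `spec$seed + rep_index - 1`.
#' @return List with `X` (an [expression_matrix()], 200 x 15),
#'   `true_gene_clusters` and `true_contexts`.
#' @export
#'
#' @examples
#' d <- generate_scenario(simulation_spec("A", sigma = 0.5, seed = 7))
#' dim(d$X)
generate_scenario <- function(spec, rep_index = 1L) {
  mu <- sim_mean_matrix(spec$scenario)
  set.seed(spec$seed + rep_index - 1L)
  X <- mu + matrix(rnorm(length(mu), sd = spec$sigma), nrow(mu), ncol(mu))
  list(X = expression_matrix(X,
                             gene_ids = sprintf("gene_%03d", seq_len(nrow(mu))),
                             sample_ids = sprintf("sample_%02d",
                                                  seq_len(ncol(mu)))),
       true_gene_clusters = planted_gene_clusters(),
       true_contexts = planted_contexts())
}

#' ROC of context recovery over all tree-cut levels
#'
#' Cuts a sample dendrogram at every level `k = 1..M`; at each level a pair
#' of samples counts as a true positive if it is co-clustered and truly
#' shares a context, and as a false positive if co-clustered across
#' contexts.  The area under the (FPR, TPR) curve is computed by the
#' trapezoid rule with (0,0) and (1,1) appended.
#'
#' @param tree Sample dendrogram (`hclust`/`merge_tree`).
#' @param truth Integer vector of true context labels, one per leaf, in leaf
#'   input order; must contain at least 2 distinct contexts.
#' @return List of class `"roc_result"` with `points` (data.frame `k`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_points <- function(tree, truth) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust/merge_tree")
  m <- length(tree$order)
  truth <- as.integer(truth)
  if (length(truth) != m) stop("truth must label every leaf")
  if (length(unique(truth)) < 2L)
    stop("truth must contain at least two contexts")
  same <- outer(truth, truth, "==")
  ut <- upper.tri(same)
  n_pos <- sum(same[ut]); n_neg <- sum(!same[ut])
  pts <- data.frame(k = seq_len(m), fpr = NA_real_, tpr = NA_real_)
  for (k in seq_len(m)) {
    lab <- cutree(tree, k = k)
    co <- outer(lab, lab, "==")
    pts$tpr[k] <- sum(co[ut] & same[ut]) / n_pos
    pts$fpr[k] <- sum(co[ut] & !same[ut]) / n_neg
  }
  o <- order(pts$fpr, pts$tpr)
  fpr <- c(0, pts$fpr[o], 1)
  tpr <- c(0, pts$tpr[o], 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' Distance-based average-linkage sample tree (baseline methods)
#'
#' Traditional hierarchical clustering of samples by expression-level
#' similarity: average linkage on either Euclidean distance between sample
#' columns or `1 - Pearson` correlation.
#'
#' @param X An [expression_matrix()].
#' @param metric `"euclidean"` or `"pearson"`.
#' @return An `hclust` tree over samples, of class `"merge_tree"`.
#' @export
baseline_tree <- function(X, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  X <- as_expression_matrix(X)
  if (metric == "euclidean") {
    d <- dist(t(unclass(X)))
  } else {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("Pearson baseline undefined: sample column(s) ",
           paste(colnames(X)[sds == 0], collapse = ", "),
           " have zero variance")
    d <- as.dist(1 - cor(unclass(X)))
  }
  tree <- hclust(d, method = "average")
  class(tree) <- c("merge_tree", class(tree))
  tree
}

#' Benchmark context recovery of the model against baseline clusterings
#'
#' For each replicate dataset the sample tree of every method is scored
#' against the planted contexts with [roc_points()].  The model's tree is the
#' average-linkage dendrogram of the sample PPP matrix from a free-context
#' chain; baselines cluster samples by Euclidean or Pearson expression
#' similarity.
#'
#' @param spec A [simulation_spec()].
#' @param methods Subset of `c("dcim", "euclidean", "pearson")`.
#' @param config Chain settings for the model fits; the replicate seed
#'   overrides `config$seed`.  Defaults to benchmark-scale chains
#'   (300 burn-in, 700 kept sweeps).
#' @param prior,conc Model prior settings; `prior = NULL` uses empirical
#'   Bayes defaults per replicate.
#' @return List of class `"benchmark_result"`: `summary` (data.frame with
#'   method, scenario, sigma, mean/sd AUC), `auc` (reps x methods matrix),
#'   and `mean_roc` (per method, level-wise mean FPR/TPR across reps).
#' @export
run_benchmark <- function(spec,
                          methods = c("dcim", "euclidean", "pearson"),
                          config = chain_config(n_burnin = 300L,
                                                n_keep = 700L,
                                                track_local = "none"),
                          prior = NULL, conc = concentrations()) {
  methods <- match.arg(methods, several.ok = TRUE)
  aucs <- matrix(NA_real_, spec$reps, length(methods),
                 dimnames = list(NULL, methods))
  roc_acc <- lapply(methods, function(m) NULL)
  names(roc_acc) <- methods
  for (rep_i in seq_len(spec$reps)) {
    d <- generate_scenario(spec, rep_i)
    for (m in methods) {
      tree <- if (m == "dcim") {
        cfg <- config
        cfg$seed <- spec$seed + rep_i - 1L
        pr <- prior %||% conjugate_prior(d$X)
        fit <- run_chain(d$X, cfg, pr, conc)
        average_linkage(ppp_from_counts(fit$co_sample_counts, fit$n_kept))
      } else {
        baseline_tree(d$X, m)
      }
      roc <- roc_points(tree, d$true_contexts)
      aucs[rep_i, m] <- roc$auc
      roc_acc[[m]] <- if (is.null(roc_acc[[m]])) {
        roc$points[, c("fpr", "tpr")]
      } else {
        roc_acc[[m]] + roc$points[, c("fpr", "tpr")]
      }
    }
  }
  mean_roc <- lapply(roc_acc, function(p) {
    p <- p / spec$reps
    p$k <- seq_len(nrow(p))
    p[, c("k", "fpr", "tpr")]
  })
  summary <- data.frame(method = methods,
                        scenario = spec$scenario,
                        sigma = spec$sigma,
                        mean_auc = colMeans(aucs),
                        sd_auc = apply(aucs, 2, stats::sd),
                        row.names = NULL)
  structure(list(summary = summary, auc = aucs, mean_roc = mean_roc,
                 spec = spec),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark: scenario %s, sigma = %.2f, %d reps\n",
              x$spec$scenario, x$spec$sigma, x$spec$reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
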