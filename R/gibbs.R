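#' Configuration for the collapsed Gibbs sampler
#'
#' @param n_burnin Number of discarded warm-up sweeps.
#' @param n_keep Number of kept sweeps; co-grouping counts accumulate over
#'   every kept sweep.
#' @param thin Keep every `thin`-th allocation snapshot in `kept_draws`
#'   (counts are unaffected by thinning).
#' @param seed Integer seed; every random draw in the chain flows from it.
#' @param resample_concentrations If `TRUE`, the three DP concentrations are
#'   resampled each sweep under a Gamma(1, 1) hyperprior (off by default).
#' @param fixed_contexts Optional length-M integer vector of context labels
#'   (contiguous, starting at 1).  When supplied the sample-to-context
#'   allocation is frozen and only genes and local clusters are updated; this
#'   is how context-local co-clustering probabilities are estimated.
#' @param track_local One of `"auto"`, `"context"`, `"sample"`, `"none"`:
#'   whether to accumulate local co-clustering counts pooled per fixed
#'   context, per sample, or not at all.  `"auto"` picks `"context"` when
#'   `fixed_contexts` is given and `"sample"` otherwise.
#' @param prior_only If `TRUE` the likelihood is switched off and the chain
#'   samples from the allocation priors (for calibration checks).
#' @param n_aux Number of auxiliary candidate contexts used when proposing a
#'   new context (auxiliary-component scheme for non-conjugate DP mixtures).
#'
#' @return An object of class `"chain_config"`.
#' @export
chain_config <- function(n_burnin = 500L, n_keep = 2000L, thin = 1L,
                         seed = 1L, resample_concentrations = FALSE,
                         fixed_contexts = NULL,
                         track_local = c("auto", "context", "sample", "none"),
                         prior_only = FALSE, n_aux = 3L) {
  track_local <- match.arg(track_local)
  if (thin < 1L) stop("thin must be >= 1")
  if (n_keep < 1L) stop("n_keep must be >= 1")
  if (n_burnin < 0L) stop("n_burnin must be >= 0")
  if (n_aux < 1L) stop("n_aux must be >= 1")
  if (!is.null(fixed_contexts)) {
    fixed_contexts <- as.integer(fixed_contexts)
    labs <- sort(unique(fixed_contexts))
    if (!identical(labs, seq_along(labs)))
      stop("fixed_contexts must use contiguous labels 1..R")
  }
  structure(list(n_burnin = as.integer(n_burnin),
                 n_keep = as.integer(n_keep), thin = as.integer(thin),
                 seed = as.integer(seed),
                 resample_concentrations = isTRUE(resample_concentrations),
                 fixed_contexts = fixed_contexts,
                 track_local = track_local,
                 prior_only = isTRUE(prior_only),
                 n_aux = as.integer(n_aux)),
            class = "chain_config")
}

#' Initial allocation state of the sampler
#'
#' Every gene starts in its own global cluster; all samples start in a single
#' context (or in the supplied fixed contexts); each context starts with the
#' identity local clustering (every global cluster its own local cluster).
#'
#' @param X An [expression_matrix()].
#' @param config A [chain_config()].
#' @return A list with elements `C` (gene labels), `D` (context labels),
#'   `L` (per-context local labels of global clusters), `Q` and `R`.
#' @export
initialize_state <- function(X, config = chain_config()) {
  X <- as_expression_matrix(X)
  N <- nrow(X); M <- ncol(X)
  D <- config$fixed_contexts %||% rep(1L, M)
  if (length(D) != M) stop("fixed_contexts must have one label per sample")
  R <- max(D)
  list(C = seq_len(N), D = D,
       L = lapply(seq_len(R), function(r) seq_len(N)),
       Q = N, R = R)
}

#' Run the collapsed Gibbs sampler
#'
#' Performs `n_burnin` discarded sweeps followed by `n_keep` kept sweeps.
#' Each sweep updates, in order: every gene's global-cluster allocation,
#' every (global cluster, context) local allocation, and (unless contexts are
#' fixed) every sample's context allocation.  All cluster means/variances are
#' integrated out, so each update is a closed-form categorical draw.
#' Co-grouping counts are accumulated at every kept sweep.
#'
#' @param X An [expression_matrix()] (or coercible matrix).
#' @param config A [chain_config()].
#' @param prior A [conjugate_prior()]; defaults to empirical Bayes from `X`.
#' @param conc A [concentrations()] object.
#'
#' @return An object of class `"chain_summary"`: a list with
#'   `co_gene_counts` (N x N), `co_sample_counts` (M x M),
#'   `co_local_counts` (list of N x N matrices, per fixed context or per
#'   sample), `n_kept`, `kept_draws` (thinned allocation snapshots),
#'   concentration traces, and the `config`/`prior`/`conc` used.
#' @export
#'
#' @examples
#' X <- expression_matrix(matrix(rnorm(20), 5, 4))
#' fit <- run_chain(X, chain_config(n_burnin = 10, n_keep = 50, seed = 1))
#' range(ppp_from_counts(fit$co_gene_counts, fit$n_kept)$values)
run_chain <- function(X, config = chain_config(),
                      prior = conjugate_prior(X),
                      conc = concentrations()) {
  X <- as_expression_matrix(X)
  N <- nrow(X); M <- ncol(X)
  m0 <- prior$m0
  if (length(m0) == 1L) m0 <- rep(m0, M)
  if (length(m0) != M) stop("prior m0 must have one entry per sample")
  fixed <- config$fixed_contexts %||% integer(0)
  if (length(fixed) > 0L && length(fixed) != M)
    stop("fixed_contexts must have one label per sample")
  track <- config$track_local
  if (track == "auto") track <- if (length(fixed)) "context" else "sample"

  set.seed(config$seed)
  res <- .dcim_chain_cpp(unclass(X), m0, prior$lambda, prior$a, prior$tau,
                         conc$alpha, conc$beta, conc$phi,
                         config$n_burnin, config$n_keep, config$thin,
                         as.integer(fixed),
                         config$prior_only,
                         config$resample_concentrations,
                         track, config$n_aux, FALSE)
  gid <- rownames(X); sid <- colnames(X)
  dimnames(res$co_gene_counts) <- list(gid, gid)
  dimnames(res$co_sample_counts) <- list(sid, sid)
  if (length(res$co_local_counts)) {
    res$co_local_counts <- lapply(res$co_local_counts, function(m) {
      dimnames(m) <- list(gid, gid); m
    })
    names(res$co_local_counts) <-
      if (track == "context") paste0("context_", seq_along(res$co_local_counts))
      else sid
  }
  res$gene_ids <- gid
  res$sample_ids <- sid
  res$config <- config
  res$prior <- prior
  res$conc <- conc
  res$track_local <- track
  class(res) <- "chain_summary"
  res
}

#' @export
print.chain_summary <- function(x, ...) {
  nQ <- mean(vapply(x$kept_draws, function(d) length(unique(d$C)), 1))
  nR <- mean(vapply(x$kept_draws, function(d) length(unique(d$D)), 1))
  cat(sprintf(
    "chain_summary: %d genes x %d samples, %d kept sweeps (seed %d)\n",
    nrow(x$co_gene_counts), nrow(x$co_sample_counts), x$n_kept,
    x$config$seed))
  cat(sprintf("  mean global gene clusters: %.2f; mean contexts: %.2f\n",
              nQ, nR))
  invisible(x)
}

# internal: consistency run with per-sweep rebuilt-statistics checks
chain_debug_max_error <- function(X, config, prior = conjugate_prior(X),
                                  conc = concentrations()) {
  X <- as_expression_matrix(X)
  m0 <- prior$m0
  if (length(m0) == 1L) m0 <- rep(m0, ncol(X))
  fixed <- config$fixed_contexts %||% integer(0)
  set.seed(config$seed)
  res <- .dcim_chain_cpp(unclass(X), m0, prior$lambda, prior$a, prior$tau,
                         conc$alpha, conc$beta, conc$phi,
                         config$n_burnin, config$n_keep, config$thin,
                         as.integer(fixed), config$prior_only,
                         config$resample_concentrations, "none",
                         config$n_aux, TRUE)
  res$max_stat_error
}

#' Resample a Dirichlet-process concentration parameter
#'
#' One draw of the auxiliary-variable update for a DP concentration given the
#' number of occupied groups `k` among `n` items, under a Gamma(shape, rate)
#' hyperprior.
#'
#' @param current Current concentration value.
#' @param k Number of occupied groups.
#' @param n Number of allocated items.
#' @param shape,rate Gamma hyperprior parameters (default 1, 1).
#' @return A positive draw.
#' @export
resample_dp_concentration <- function(current, k, n, shape = 1, rate = 1) {
  if (current <= 0) stop("current concentration must be positive")
  .dp_conc_draw_cpp(current, as.integer(k), as.integer(n), shape, rate)
}
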