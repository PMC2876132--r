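#' Conjugate Normal-Inverse-Gamma prior for expression patterns
#'
#' The model integrates the mean and variance of every (local cluster,
#' context, sample) dimension out analytically under an independent
#' Normal-Inverse-Gamma prior: `mu | sigma2 ~ N(m0, sigma2 / lambda)` and
#' `sigma2 ~ Inv-Gamma(a, tau)`.  Defaults are empirical Bayes: `m0` is the
#' per-sample column mean and `tau` the overall variance of the data, so the
#' prior is weakly informative on the scale of the data.
#'
#' @param X Optional expression matrix used for the empirical defaults.
#' @param m0 Per-sample prior mean vector (recycled if scalar).
#' @param lambda Prior precision scale (> 0); number of pseudo-observations
#'   backing `m0`.
#' @param a Inverse-gamma shape (> 0).
#' @param tau Inverse-gamma scale (> 0); with `a = 2` the prior mean of the
#'   noise variance equals `tau`.
#'
#' @return An object of class `"conjugate_prior"`.
#' @export
conjugate_prior <- function(X = NULL, m0 = NULL, lambda = 1, a = 2,
                            tau = NULL) {
  if (!is.null(X)) {
    X <- as_expression_matrix(X)
    if (is.null(m0)) m0 <- colMeans(X)
    if (is.null(tau)) tau <- var(as.vector(X))
  }
  if (is.null(m0)) m0 <- 0
  if (is.null(tau)) tau <- 1
  if (!all(is.finite(m0))) stop("m0 must be finite")
  if (lambda <= 0 || a <= 0 || tau <= 0)
    stop("lambda, a and tau must be strictly positive")
  structure(list(m0 = as.numeric(m0), lambda = lambda, a = a, tau = tau),
            class = "conjugate_prior")
}

#' Dirichlet-process concentration parameters
#'
#' One concentration per allocation level: `alpha` for genes into global
#' clusters, `beta` for samples into contexts, `phi` for global clusters into
#' context-local clusters.
#'
#' @param alpha,beta,phi Strictly positive concentrations (default 1).
#' @return An object of class `"dcim_concentrations"`.
#' @export
concentrations <- function(alpha = 1, beta = 1, phi = 1) {
  if (any(c(alpha, beta, phi) <= 0))
    stop("concentrations must be strictly positive")
  structure(list(alpha = alpha, beta = beta, phi = phi),
            class = "dcim_concentrations")
}

#' Chinese-restaurant-process allocation probabilities
#'
#' The prior probability that a new item joins each existing group, or opens
#' a new one, under a Dirichlet-process prior: an existing group of size
#' `n_k` is chosen with probability `n_k / (n + conc)` and a new group with
#' probability `conc / (n + conc)`, where `n` is the number of items already
#' allocated.  The same functional form governs all three allocation levels
#' of the model.
#'
#' @param group_sizes Non-negative integer vector of current group sizes.
#' @param concentration Strictly positive concentration parameter.
#' @param excluded_total Total count the sizes refer to; must equal
#'   `sum(group_sizes)`.
#'
#' @return Numeric probability vector of length `length(group_sizes) + 1`;
#'   the last entry is the new-group probability.  Sums to 1.
#' @export
#'
#' @examples
#' crp_weights(c(3, 1), 1, 4)  # 0.6 0.2 0.2
crp_weights <- function(group_sizes, concentration, excluded_total) {
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  if (concentration <= 0) stop("concentration must be strictly positive")
  if (sum(group_sizes) != excluded_total)
    stop("group_sizes must sum to excluded_total")
  c(group_sizes, concentration) / (excluded_total + concentration)
}

prior_slice <- function(prior, j = 1L) {
  m0 <- prior$m0
  if (length(m0) > 1L) m0 <- m0[j]
  list(m0 = m0, lambda = prior$lambda, a = prior$a, tau = prior$tau)
}

#' Log marginal likelihood of Gaussian data under the conjugate prior
#'
#' Closed form of `log integral prod_v N(v | mu, sigma2) NIG(mu, sigma2) dmu
#' dsigma2` for one data dimension.  The empty set has log marginal 0.
#'
#' @param values Numeric vector of observations (possibly empty).
#' @param prior A [conjugate_prior()]; a vector `m0` is sliced with `j`.
#' @param j Sample index selecting the `m0` component (default 1).
#' @return Log marginal likelihood (scalar).
#' @export
nig_log_marginal <- function(values, prior, j = 1L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  p <- prior_slice(prior, j)
  .nig_logm_cpp(values, p$m0, p$lambda, p$a, p$tau)
}

#' Log posterior-predictive density under the conjugate prior
#'
#' The posterior predictive of a Normal-Inverse-Gamma model is a Student-t
#' with `2 * a_n` degrees of freedom; this returns its log density at `x`
#' given sufficient statistics of previously observed values.  Satisfies
#' `nig_log_marginal(c(S, x)) - nig_log_marginal(S) = nig_log_predictive(x, S)`
#' exactly.
#'
#' @param x Scalar observation.
#' @param stats Either a numeric vector of observed values or a list with
#'   elements `n`, `s1` (sum) and `s2` (sum of squares).  Empty/NULL means
#'   the prior predictive.
#' @inheritParams nig_log_marginal
#' @return Log predictive density (scalar).
#' @export
nig_log_predictive <- function(x, stats = NULL, prior, j = 1L) {
  p <- prior_slice(prior, j)
  if (is.null(stats) || (is.numeric(stats) && length(stats) == 0L)) {
    s <- list(n = 0, s1 = 0, s2 = 0)
  } else if (is.numeric(stats)) {
    s <- list(n = length(stats), s1 = sum(stats), s2 = sum(stats^2))
  } else {
    s <- stats
    if (s$n > 0 && s$s2 < s$s1^2 / s$n - 1e-8)
      stop("inconsistent sufficient statistics: s2 < s1^2/n")
  }
  .nig_logpred_cpp(x, s$n, s$s1, s$s2, p$m0, p$lambda, p$a, p$tau)
}
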