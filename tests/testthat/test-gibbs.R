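test_that("initial state: singleton genes, one context, identity locals", {
  X <- expression_matrix(matrix(rnorm(6), 3, 2))
  st <- initialize_state(X)
  expect_equal(st$C, 1:3)
  expect_equal(st$D, c(1L, 1L))
  expect_equal(st$L[[1]], 1:3)
  st2 <- initialize_state(expression_matrix(matrix(rnorm(8), 2, 4)),
                          chain_config(fixed_contexts = c(1, 1, 2, 2)))
  expect_equal(st2$D, c(1L, 1L, 2L, 2L))
  expect_equal(st2$R, 2L)
})

test_that("fixed contexts are never updated and label checks apply", {
  X <- expression_matrix(matrix(rnorm(40), 5, 8))
  cfg <- chain_config(n_burnin = 20, n_keep = 60, seed = 5,
                      fixed_contexts = rep(1:2, each = 4))
  fit <- run_chain(X, cfg)
  for (d in fit$kept_draws)
    expect_equal(d$D, rep(1:2, each = 4))
  expect_error(chain_config(fixed_contexts = c(1, 3)), "contiguous")
})

test_that("identical seed and config give bit-identical chains", {
  X <- expression_matrix(matrix(rnorm(60), 10, 6))
  cfg <- chain_config(n_burnin = 30, n_keep = 80, seed = 99)
  f1 <- run_chain(X, cfg)
  f2 <- run_chain(X, cfg)
  expect_identical(f1$co_gene_counts, f2$co_gene_counts)
  expect_identical(f1$co_sample_counts, f2$co_sample_counts)
  expect_identical(f1$co_local_counts, f2$co_local_counts)
  expect_identical(f1$kept_draws, f2$kept_draws)
})

test_that("count matrices are symmetric with diagonal n_kept", {
  X <- expression_matrix(matrix(rnorm(48), 8, 6))
  fit <- run_chain(X, chain_config(n_burnin = 20, n_keep = 70, seed = 3))
  for (m in c(list(fit$co_gene_counts, fit$co_sample_counts),
              fit$co_local_counts)) {
    expect_identical(m, t(m))
    expect_true(all(diag(m) == fit$n_kept))
    expect_true(all(m >= 0 & m <= fit$n_kept))
  }
})

test_that("two near-identical genes are co-clustered in almost all draws", {
  set.seed(10)
  base <- rnorm(3, sd = 2)
  X <- expression_matrix(rbind(base + rnorm(3, sd = 0.01),
                               base + rnorm(3, sd = 0.01),
                               -base + rnorm(3, sd = 0.01)))
  # prior scale matched to the (tiny) within-gene noise, not to the spread
  # of the patterns, so indistinguishable genes should coalesce.  phi is
  # large so the posterior cannot park the pair in two global clusters that
  # are merged locally (which carries the same likelihood).
  prior <- conjugate_prior(m0 = 0, lambda = 0.1, a = 2, tau = 0.05)
  conc <- concentrations(phi = 50)
  fit <- run_chain(X, chain_config(n_burnin = 100, n_keep = 2000, seed = 1),
                   prior, conc)
  ppp <- ppp_from_counts(fit$co_gene_counts, fit$n_kept)$values
  exact <- enumerate_posterior(unclass(X), prior, conc)
  expect_gt(exact$gene_ppp[1, 2], 0.95)  # the posterior itself demands it
  expect_gt(ppp[1, 2], 0.95)
  expect_lt(max(abs(ppp - exact$gene_ppp)), 0.03)
  expect_lt(ppp[1, 3], 0.5)
})

test_that("prior-only chains recover CRP expected group counts", {
  X <- expression_matrix(matrix(rnorm(20 * 8), 20, 8))
  conc <- concentrations(alpha = 1.5, beta = 0.8, phi = 1)
  cfg <- chain_config(n_burnin = 100, n_keep = 4000, thin = 10, seed = 17,
                      prior_only = TRUE, track_local = "none")
  fit <- run_chain(X, cfg, conc = conc)
  nQ <- vapply(fit$kept_draws, function(d) length(unique(d$C)), 1)
  nR <- vapply(fit$kept_draws, function(d) length(unique(d$D)), 1)
  for (case in list(list(x = nQ, mu = crp_expected_groups(20, 1.5)),
                    list(x = nR, mu = crp_expected_groups(8, 0.8)))) {
    se <- stats::sd(case$x) / sqrt(length(case$x))
    expect_lt(abs(mean(case$x) - case$mu), 3 * se + 1e-12)
  }
})

test_that("incremental sufficient statistics match from-scratch rebuilds", {
  set.seed(6)
  X <- expression_matrix(matrix(rnorm(15 * 6, sd = 2), 15, 6))
  err <- dcim:::chain_debug_max_error(
    X, chain_config(n_burnin = 50, n_keep = 150, seed = 8))
  expect_lt(err, 1e-8)
  # also with fixed contexts (gene + local moves only)
  err2 <- dcim:::chain_debug_max_error(
    X, chain_config(n_burnin = 50, n_keep = 100, seed = 9,
                    fixed_contexts = rep(1:2, each = 3)))
  expect_lt(err2, 1e-8)
})

test_that("local clustering merges equal-mean global clusters more often", {
  set.seed(11)
  n <- 6
  # genes in two blocks; blocks share their mean pattern -> indistinguishable
  base <- c(2, 2, 2, 2)
  Xsame <- rbind(matrix(rep(base, n), n, byrow = TRUE) + rnorm(4 * n, sd = .3),
                 matrix(rep(base, n), n, byrow = TRUE) + rnorm(4 * n, sd = .3))
  # well-separated block means
  Xfar <- rbind(matrix(rep(base, n), n, byrow = TRUE) + rnorm(4 * n, sd = .3),
                matrix(rep(-base, n), n, byrow = TRUE) + rnorm(4 * n, sd = .3))
  co_local_rate <- function(X) {
    fit <- run_chain(expression_matrix(X),
                     chain_config(n_burnin = 100, n_keep = 300, seed = 4,
                                  fixed_contexts = rep(1L, 4)))
    ppp <- ppp_from_counts(fit$co_local_counts[[1]], fit$n_kept)$values
    mean(ppp[1:n, n + (1:n)])
  }
  expect_gt(co_local_rate(Xsame), co_local_rate(Xfar))
})

test_that("Gibbs co-grouping matches exhaustive enumeration on 3x3", {
  X <- oracle_instance(N = 3, M = 3, seed = 21, sigma = 0.6)
  prior <- conjugate_prior(X)
  conc <- concentrations()
  exact <- enumerate_posterior(unclass(X), prior, conc)
  fit <- run_chain(X, chain_config(n_burnin = 500, n_keep = 20000, seed = 2,
                                   track_local = "none"), prior, conc)
  g <- ppp_from_counts(fit$co_gene_counts, fit$n_kept)$values
  s <- ppp_from_counts(fit$co_sample_counts, fit$n_kept)$values
  expect_lt(max(abs(g - exact$gene_ppp)), 0.03)
  expect_lt(max(abs(s - exact$sample_ppp)), 0.03)
})

test_that("concentration resampling stays positive and tracks cluster count", {
  # disabled: concentrations pass through untouched
  X <- expression_matrix(matrix(rnorm(30), 6, 5))
  fit <- run_chain(X, chain_config(n_burnin = 10, n_keep = 30, seed = 1))
  expect_true(all(fit$alpha_trace == 1))
  expect_true(all(fit$beta_trace == 1))
  # enabled: all draws strictly positive
  fit2 <- run_chain(X, chain_config(n_burnin = 10, n_keep = 200, seed = 2,
                                    resample_concentrations = TRUE))
  expect_true(all(fit2$alpha_trace > 0))
  expect_true(all(fit2$beta_trace > 0))
  expect_true(all(fit2$phi_trace > 0))
  # one big group pulls alpha down relative to all-singletons
  set.seed(30)
  d_small <- mean(replicate(800, resample_dp_concentration(1, k = 1, n = 12)))
  d_large <- mean(replicate(800, resample_dp_concentration(1, k = 12, n = 12)))
  expect_lt(d_small, d_large)
})
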