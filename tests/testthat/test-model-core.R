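test_that("expression_matrix validates its inputs", {
  v <- matrix(rnorm(12), 4, 3)
  X <- expression_matrix(v)
  expect_s3_class(X, "expression_matrix")
  expect_equal(rownames(X), paste0("gene_", 1:4))
  expect_error(expression_matrix(matrix(1, 1, 3)), "at least 2")
  v[2, 2] <- NA
  expect_error(expression_matrix(v), "missing")
  expect_error(expression_matrix(matrix(rnorm(4), 2, 2),
                                 gene_ids = c("a", "a")), "duplicate gene")
  expect_error(expression_matrix(matrix(rnorm(4), 2, 2),
                                 sample_ids = c("s", "s")),
               "duplicate sample")
})

test_that("crp_weights matches the CRP formula and normalizes", {
  expect_equal(crp_weights(c(3, 1), 1, 4), c(0.6, 0.2, 0.2))
  expect_equal(crp_weights(integer(0), 2, 0), 1)
  w <- crp_weights(5, 1e-9, 5)
  expect_equal(w[1], 1, tolerance = 1e-8)
  expect_lt(w[2], 1e-9)
  # probability vector for random configurations
  set.seed(1)
  for (i in 1:25) {
    sizes <- sample(0:6, sample(1:5, 1), replace = TRUE)
    conc <- runif(1, 0.01, 10)
    w <- crp_weights(sizes, conc, sum(sizes))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_error(crp_weights(c(-1, 2), 1, 1), "non-negative")
  expect_error(crp_weights(c(1, 2), 0, 3), "positive")
  expect_error(crp_weights(c(1, 2), 1, 4), "sum")
})

test_that("nig_log_marginal matches 2D numerical quadrature", {
  prior <- conjugate_prior(m0 = 0, lambda = 1, a = 2, tau = 1)
  # integrand over (mu, sigma2): prod N(v | mu, s2) * NIG(mu, s2)
  quad_marginal <- function(values, m0, lambda, a, tau) {
    f <- function(s2) {
      vapply(s2, function(s) {
        g <- function(mu) {
          vapply(mu, function(m) {
            exp(sum(dnorm(values, m, sqrt(s), log = TRUE)) +
                  dnorm(m, m0, sqrt(s / lambda), log = TRUE))
          }, 1)
        }
        ig <- a * log(tau) - lgamma(a) - (a + 1) * log(s) - tau / s
        integrate(g, -20, 20, rel.tol = 1e-10)$value * exp(ig)
      }, 1)
    }
    log(integrate(f, 1e-4, 200, rel.tol = 1e-10)$value)
  }
  expect_equal(nig_log_marginal(0.7, prior),
               quad_marginal(0.7, 0, 1, 2, 1), tolerance = 1e-6)
  expect_equal(nig_log_marginal(c(0.3, -1.2, 0.5), prior),
               quad_marginal(c(0.3, -1.2, 0.5), 0, 1, 2, 1),
               tolerance = 1e-6)
  pr2 <- conjugate_prior(m0 = 1.5, lambda = 0.5, a = 3, tau = 2)
  expect_equal(nig_log_marginal(c(2.0, 1.1), pr2),
               quad_marginal(c(2.0, 1.1), 1.5, 0.5, 3, 2), tolerance = 1e-6)
})

test_that("nig_log_marginal: empty set, shift and permutation invariance", {
  prior <- conjugate_prior(m0 = 0, lambda = 1, a = 2, tau = 1)
  expect_identical(nig_log_marginal(numeric(0), prior), 0)
  set.seed(2)
  v <- rnorm(7)
  for (c_shift in c(-3, 0.5, 10)) {
    shifted <- conjugate_prior(m0 = c_shift, lambda = 1, a = 2, tau = 1)
    expect_equal(nig_log_marginal(v + c_shift, shifted),
                 nig_log_marginal(v, prior), tolerance = 1e-9)
  }
  expect_equal(nig_log_marginal(sample(v), prior), nig_log_marginal(v, prior))
})

test_that("predictive is the marginal increment and the prior-predictive t", {
  prior <- conjugate_prior(m0 = 0.3, lambda = 2, a = 2.5, tau = 1.4)
  # empty stats: Student-t with 2a df, location m0, scale sqrt(tau(l+1)/(a l))
  x <- 0.9
  scale <- sqrt(1.4 * 3 / (2.5 * 2))
  expect_equal(nig_log_predictive(x, NULL, prior),
               dt((x - 0.3) / scale, df = 5, log = TRUE) - log(scale))
  # chain identity on random (S, x) draws
  set.seed(3)
  for (i in 1:20) {
    S <- rnorm(sample(1:12, 1), sd = runif(1, 0.2, 3))
    xx <- rnorm(1)
    expect_equal(nig_log_marginal(c(S, xx), prior) - nig_log_marginal(S, prior),
                 nig_log_predictive(xx, S, prior), tolerance = 1e-10)
  }
})

test_that("predictive concentrates on the data law as n grows", {
  prior <- conjugate_prior(m0 = 0, lambda = 1, a = 2, tau = 1)
  set.seed(4)
  S <- rnorm(20000, mean = 2, sd = 0.5)
  dens <- function(x)
    exp(vapply(x, nig_log_predictive, 1, stats = S, prior = prior))
  xs <- seq(-2, 6, length.out = 4001)
  px <- dens(xs)
  dx <- xs[2] - xs[1]
  m <- sum(xs * px) * dx
  v <- sum((xs - m)^2 * px) * dx
  expect_equal(m, 2, tolerance = 0.02)
  expect_equal(v, 0.25, tolerance = 0.02)
})

test_that("prior constructors reject invalid parameters", {
  expect_error(conjugate_prior(m0 = 0, lambda = 0), "positive")
  expect_error(conjugate_prior(m0 = Inf), "finite")
  expect_error(concentrations(alpha = -1), "positive")
  expect_error(nig_log_predictive(1, list(n = 2, s1 = 4, s2 = 1),
                                  conjugate_prior()),
               "inconsistent")
})
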