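make_ppp <- function(m, ids = NULL) {
  ids <- ids %||% paste0("g", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  dcim:::as_ppp_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

block_ppp <- function(n, blocks, hi = 0.95, lo = 0.05) {
  p <- matrix(lo, n, n)
  for (b in blocks) p[b, b] <- hi
  diag(p) <- 1
  p
}

test_that("diff_matrix is the elementwise absolute difference", {
  p1 <- make_ppp(block_ppp(4, list(1:2, 3:4), hi = 0.9, lo = 0.2))
  p2 <- make_ppp(block_ppp(4, list(1:2, 3:4), hi = 0.9, lo = 0.2))
  expect_true(all(diff_matrix(p1, p2) == 0))
  p3 <- make_ppp(block_ppp(4, list(1:3), hi = 0.9, lo = 0.2))
  d <- diff_matrix(p1, p3)
  expect_equal(d[1, 3], abs(0.2 - 0.9))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(diff_matrix(p1, make_ppp(block_ppp(5, list(1:2)))),
               "dimensions")
})

test_that("dcs_for_cluster follows the printed mean formula", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.5
  d[1, 3] <- d[3, 1] <- 0.3
  expect_equal(dcs_for_cluster(1, 1:3, d), 0.4)
  expect_equal(dcs_for_cluster(2, c(1, 3), d), 0)   # i not in g
  expect_equal(dcs_for_cluster(1, 1, d), 0)         # singleton guard
  # adding a gene whose difference equals the current mean leaves the
  # score unchanged
  d4 <- matrix(0, 4, 4)
  d4[1, 2] <- d4[2, 1] <- 0.5
  d4[1, 3] <- d4[3, 1] <- 0.3
  d4[1, 4] <- d4[4, 1] <- 0.4
  expect_equal(dcs_for_cluster(1, 1:4, d4), dcs_for_cluster(1, 1:3, d4))
})

test_that("dcs_genes scores 0 when local PPPs agree and is order-invariant", {
  set.seed(14)
  m <- matrix(runif(36, 0, 0.8), 6, 6)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  p <- make_ppp(m)
  res <- dcs_genes(p, p)
  expect_true(all(res$score == 0))
  expect_equal(sort(res$rank), 1:6)

  # permuting gene order permutes the scores accordingly
  p1 <- make_ppp(block_ppp(6, list(1:3, 4:6)))
  p2 <- make_ppp(block_ppp(6, list(1:2, 3:6)))
  res1 <- dcs_genes(p1, p2)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  pp1 <- make_ppp(p1$values[perm, perm], p1$item_ids[perm])
  pp2 <- make_ppp(p2$values[perm, perm], p2$item_ids[perm])
  res2 <- dcs_genes(pp1, pp2)
  expect_equal(res2$score[match(res1$gene_id, res2$gene_id)], res1$score)
})

test_that("dcs_genes finds the genes whose partners change", {
  # context 1: {1,2,3} vs {4,5,6}; context 2: gene 3 defects to the others
  p1 <- make_ppp(block_ppp(6, list(1:3, 4:6)))
  p2 <- make_ppp(block_ppp(6, list(1:2, 3:6)))
  res <- dcs_genes(p1, p2)
  expect_gt(res$score[3], max(res$score[c(1, 2)]))
  expect_true(all(res$score >= 0 & res$score <= 1))
  expect_equal(res$rank[3], 1L)
  expect_true(3 %in% res$cluster[[3]])
})

test_that("local_ppp_per_context returns symmetric per-context PPPs", {
  set.seed(15)
  # same co-clustering in both contexts -> local PPPs agree within MC error
  blockmeans <- rbind(matrix(2, 3, 6), matrix(-2, 3, 6))
  X <- expression_matrix(blockmeans + matrix(rnorm(36, sd = 0.3), 6, 6))
  ctx <- rep(1:2, each = 3)
  pp <- local_ppp_per_context(
    X, ctx, chain_config(n_burnin = 100, n_keep = 400, seed = 6))
  expect_length(pp, 2)
  for (p in pp) {
    expect_s3_class(p, "ppp_matrix")
    expect_true(all(p$values >= 0 & p$values <= 1))
    expect_identical(p$values, t(p$values))
  }
  expect_lt(max(abs(pp[[1]]$values - pp[[2]]$values)), 0.05)
  # determinism under a fixed seed
  pp2 <- local_ppp_per_context(
    X, ctx, chain_config(n_burnin = 100, n_keep = 400, seed = 6))
  expect_identical(pp[[1]]$values, pp2[[1]]$values)
  expect_error(local_ppp_per_context(X, c(1, 1, 1, 1, 1, 2),
                                     chain_config()),
               "at least 2 samples")
  expect_error(local_ppp_per_context(X, rep(1:3, each = 2), chain_config()),
               "exactly 2")
})

test_that("overlap significance matches exact hypergeometric enumeration", {
  # identical 10-gene lists in a universe of 1000
  A <- paste0("g", 1:10)
  res <- overlap_significance(A, A, 1000)
  exact <- choose(990, 0) * choose(10, 10) / choose(1000, 10)
  expect_equal(res$p, exact, tolerance = 1e-12)
  expect_lt(res$p, 1e-20)
  # disjoint lists covering most of the universe: negative log-odds under
  # the Haldane correction
  B <- paste0("h", 1:10)
  res2 <- overlap_significance(A, B, 25)
  expect_lt(res2$log_odds, 0)
  expect_equal(res2$overlap, 0)
  # overlap at its expectation: log-odds near 0
  # |A| = 100, |B| = 100, universe 1000 -> expected overlap 10
  A3 <- paste0("g", 1:100)
  B3 <- c(paste0("g", 1:10), paste0("h", 1:90))
  res3 <- overlap_significance(A3, B3, 1000)
  expect_lt(abs(res3$log_odds), 0.15)
  # p is an exact tail sum
  tail_sum <- sum(vapply(10:100, function(k)
    choose(100, k) * choose(900, 100 - k) / choose(1000, 100), 1))
  expect_equal(res3$p, tail_sum, tolerance = 1e-9)
  expect_error(overlap_significance(A, B, 15), "universe")
})
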