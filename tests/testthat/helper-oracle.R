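# Independent oracles used across the test suite.
#
# The enumeration oracle computes exact posterior co-grouping probabilities
# on tiny instances by summing over every (C, D, L) configuration; the
# marginal likelihood used here is built from R's dt() via the sequential
# predictive decomposition, a code path independent of the package's closed
# form.

# all set partitions of n items as restricted-growth label vectors (1-based)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_lab) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_lab)) {
      recurse(c(labels, lab), next_lab + (lab == next_lab))
    }
  }
  recurse(integer(0), 1L)
  out
}

# CRP exchangeable partition probability
log_eppf <- function(sizes, conc) {
  n <- sum(sizes)
  length(sizes) * log(conc) + sum(lgamma(sizes)) -
    sum(log(conc + seq_len(n) - 1))
}

# marginal likelihood via sequential Student-t predictives (R dt())
oracle_logm <- function(values, m0, lambda, a, tau) {
  lp <- 0
  n <- 0; s1 <- 0
  ln <- lambda; an <- a; taun <- tau; mn <- m0
  for (x in values) {
    scale <- sqrt(taun * (ln + 1) / (an * ln))
    lp <- lp + dt((x - mn) / scale, df = 2 * an, log = TRUE) - log(scale)
    # posterior update
    taun <- taun + 0.5 * (ln / (ln + 1)) * (x - mn)^2
    mn <- (ln * mn + x) / (ln + 1)
    ln <- ln + 1
    an <- an + 0.5
  }
  lp
}

# exact posterior over (C, D, L) for a small expression matrix
# returns gene and sample co-grouping probability matrices
enumerate_posterior <- function(X, prior, conc) {
  N <- nrow(X); M <- ncol(X)
  m0 <- prior$m0
  if (length(m0) == 1L) m0 <- rep(m0, M)
  partsC <- all_partitions(N)
  partsD <- all_partitions(M)
  configs <- list()
  logps <- numeric(0)
  for (C in partsC) {
    Q <- max(C)
    eppf_C <- log_eppf(tabulate(C), conc$alpha)
    partsL <- all_partitions(Q)
    for (D in partsD) {
      R <- max(D)
      eppf_D <- log_eppf(tabulate(D), conc$beta)
      # enumerate independent local partitions per context
      Lidx <- rep(1L, R)
      nL <- length(partsL)
      repeat {
        logp <- eppf_C + eppf_D
        for (r in seq_len(R)) {
          Lr <- partsL[[Lidx[r]]]
          logp <- logp + log_eppf(tabulate(Lr), conc$phi)
          for (t in seq_len(max(Lr))) {
            genes <- which(Lr[C] == t)
            for (j in which(D == r)) {
              logp <- logp + oracle_logm(X[genes, j], m0[j], prior$lambda,
                                         prior$a, prior$tau)
            }
          }
        }
        logps[length(logps) + 1L] <- logp
        configs[[length(configs) + 1L]] <- list(C = C, D = D)
        # odometer over local partitions
        pos <- 1L
        while (pos <= R) {
          Lidx[pos] <- Lidx[pos] + 1L
          if (Lidx[pos] <= nL) break
          Lidx[pos] <- 1L
          pos <- pos + 1L
        }
        if (pos > R) break
      }
    }
  }
  w <- exp(logps - max(logps))
  w <- w / sum(w)
  gene_ppp <- matrix(0, N, N)
  sample_ppp <- matrix(0, M, M)
  for (k in seq_along(configs)) {
    C <- configs[[k]]$C; D <- configs[[k]]$D
    gene_ppp <- gene_ppp + w[k] * outer(C, C, "==")
    sample_ppp <- sample_ppp + w[k] * outer(D, D, "==")
  }
  list(gene_ppp = gene_ppp, sample_ppp = sample_ppp)
}

# naive unweighted average-linkage agglomeration on a distance matrix;
# returns merge heights (sorted) for comparison with hclust
oracle_average_linkage_heights <- function(d) {
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA); bestv <- Inf
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        v <- mean(d[groups[[a]], groups[[b]]])
        if (v < bestv - 1e-15) {
          bestv <- v; best <- c(a, b)
        }
      }
    }
    heights <- c(heights, bestv)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# CRP expected number of occupied groups for n items
crp_expected_groups <- function(n, conc) sum(conc / (conc + seq_len(n) - 1))

# tiny deterministic instance used by the enumeration tests
oracle_instance <- function(N = 4, M = 3, seed = 42, sigma = 0.5) {
  set.seed(seed)
  mu <- matrix(0, N, M)
  mu[seq_len(ceiling(N / 2)), 1:2] <- 1.5   # two gene blocks, contrast in j=1,2
  X <- mu + matrix(rnorm(N * M, sd = sigma), N, M)
  expression_matrix(X, paste0("g", seq_len(N)), paste0("s", seq_len(M)))
}
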