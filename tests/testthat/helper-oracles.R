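# Independent oracles and fixture generators used across the test suite.
# Every oracle is a deliberately naive re-implementation (enumeration,
# brute-force loops, generic numeric optimisation) kept independent of the
# package's own code paths.

# random character matrix built in code
rand_matrix <- function(n_taxa, n_char, k_range = 2:4, p_miss = 0.2,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(NA_character_, n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  for (j in seq_len(n_char)) {
    k <- sample(k_range, 1)
    x[, j] <- as.character(sample.int(k, n_taxa, replace = TRUE) - 1L)
  }
  x[runif(length(x)) < p_miss] <- NA_character_
  character_matrix(x)
}

# random time tree with all tips at age 0
rand_ttree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n)
  time_tree(phy, youngest_tip_age = 0)
}

# brute-force Gower distance by explicit per-pair loops
oracle_gower <- function(x) {
  x <- unclass(x)
  n <- nrow(x)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    comp <- 0; diff <- 0
    for (ch in seq_len(ncol(x))) {
      if (!is.na(x[i, ch]) && !is.na(x[j, ch])) {
        comp <- comp + 1
        if (x[i, ch] != x[j, ch]) diff <- diff + 1
      }
    }
    d[i, j] <- if (comp > 0) diff / comp else NA_real_
  }
  diag(d) <- 0
  d
}

# mean squared distance by explicit pair enumeration
oracle_msd <- function(dm, taxa) {
  n <- length(taxa)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + dm[taxa[i], taxa[j]]^2
    np <- np + 1
  }
  tot / np
}

# symmetric Mk transition probability
oracle_pij <- function(r, t, k, same) {
  e <- exp(-k * r * t / (k - 1))
  if (same) (1 + (k - 1) * e) / k else (1 - e) / k
}

# marginal ancestral reconstruction by exhaustive enumeration over all
# internal-state assignments; tip_states are 0-based, -1 = missing
oracle_mk_marginals <- function(phy, tip_states, k, rate) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  ntot <- ntip + nint
  grid <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L), nint)))
  probs <- apply(grid, 1, function(g) {
    st <- c(tip_states, g)
    p <- 1 / k  # uniform root prior
    for (e in seq_len(nrow(phy$edge))) {
      a <- st[phy$edge[e, 1]]; b <- st[phy$edge[e, 2]]
      t <- phy$edge.length[e]
      if (b < 0) next  # missing tip: marginalised out (sums to 1)
      p <- p * oracle_pij(rate, t, k, a == b)
    }
    p
  })
  marg <- matrix(0, ntot, k)
  for (i in seq_len(ntip))
    if (tip_states[i] >= 0) marg[i, tip_states[i] + 1] <- 1 else {
      # enumerate the missing tip state too
      for (s in seq_len(k) - 1L) {
        st2 <- tip_states; st2[i] <- s
        marg[i, s + 1] <- sum(apply(grid, 1, function(g) {
          st <- c(st2, g)
          p <- 1 / k
          for (e in seq_len(nrow(phy$edge))) {
            a <- st[phy$edge[e, 1]]; b <- st[phy$edge[e, 2]]
            if (b < 0) next
            p <- p * oracle_pij(rate, phy$edge.length[e], k, a == b)
          }
          p
        }))
      }
      marg[i, ] <- marg[i, ] / sum(marg[i, ])
    }
  for (n in seq_len(nint)) {
    for (s in seq_len(k)) {
      marg[ntip + n, s] <- sum(probs[grid[, n] == s - 1L])
    }
    marg[ntip + n, ] <- marg[ntip + n, ] / sum(marg[ntip + n, ])
  }
  marg
}

# Poisson LRT by generic numeric likelihood maximisation (lgamma form)
oracle_lrt <- function(Cf, Tf, Cr, Tr) {
  ll <- function(lam, C, T) C * log(lam * T) - lam * T - lgamma(C + 1)
  hi <- max((Cf + Cr) / min(Tf, Tr), 1) * 10 + 1
  l1 <- optimize(function(l) ll(l, Cf, Tf), c(1e-12, hi), maximum = TRUE,
                 tol = 1e-12)
  l2 <- optimize(function(l) ll(l, Cr, Tr), c(1e-12, hi), maximum = TRUE,
                 tol = 1e-12)
  l0 <- optimize(function(l) ll(l, Cf, Tf) + ll(l, Cr, Tr), c(1e-12, hi),
                 maximum = TRUE, tol = 1e-12)
  2 * (l1$objective + l2$objective - l0$objective)
}

# GLS ancestral values: for each internal node, the generalized least
# squares estimate using the re-rooted covariance built from patristic
# distances
oracle_gls_anc <- function(phy, x) {
  ntip <- length(phy$tip.label)
  D <- ape::dist.nodes(phy)
  x <- x[phy$tip.label]
  vapply((ntip + 1):(ntip + phy$Nnode), function(n) {
    V <- outer(seq_len(ntip), seq_len(ntip), function(i, j)
      (D[n, i] + D[n, j] - D[cbind(i, j)]) / 2)
    Vi <- solve(V)
    one <- rep(1, ntip)
    as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
  }, numeric(1))
}

# Spearman rho by the rank-difference formula (no ties)
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
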