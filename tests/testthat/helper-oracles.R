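# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (double loops, alternating scaling,
# exhaustive enumeration) and never calls the code paths it checks.

# symmetric random contact map with positive off-diagonal weights
random_map <- function(n, seed = 1, mask = integer()) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  contact_map(m, mask = mask)
}

# Sinkhorn-Knopp alternating row/column scaling; for symmetric positive A
# this converges to the same doubly stochastic limit as Knight-Ruiz.
sinkhorn_oracle <- function(A, iters = 5000, tol = 1e-12) {
  r <- rep(1, nrow(A))
  c <- rep(1, ncol(A))
  for (i in seq_len(iters)) {
    r_new <- 1 / as.vector(A %*% c)
    c_new <- 1 / as.vector(t(A) %*% r_new)
    if (max(abs(r_new - r), abs(c_new - c)) < tol) {
      r <- r_new; c <- c_new; break
    }
    r <- r_new; c <- c_new
  }
  diag(r) %*% A %*% diag(c)
}

# brute-force generalized modularity by explicit double loop
brute_modularity <- function(A, P, labels, gamma) {
  n <- nrow(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!is.na(labels[i]) && !is.na(labels[j]) && labels[i] == labels[j])
      q <- q + A[i, j] - gamma * P[i, j]
  }
  q / (2 * m)
}

# brute-force FG null by explicit double loops over the normalization sum
brute_fg_null <- function(A, alpha) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(k) / 2
  denom <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) denom <- denom + k[i] * k[j] * abs(i - j)^(-alpha)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) P[i, j] <- 2 * m * k[i] * k[j] * abs(i - j)^(-alpha) / denom
  P
}

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  res <- vector("list", 0)
  a <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) {
      res[[length(res) + 1]] <<- a
      return(invisible())
    }
    for (l in seq_len(maxl + 1)) {
      a[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  res
}

# exhaustive maximum of Q over all partitions of a small graph, NG null
exhaustive_best_q <- function(A, gamma = 1) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(k) / 2
  B <- A - gamma * tcrossprod(k) / (2 * m)
  diag(B) <- 0
  pr <- which(upper.tri(B), arr.ind = TRUE)
  bv <- B[pr]
  pi1 <- pr[, 1]; pi2 <- pr[, 2]
  best <- -Inf
  best_lab <- NULL
  for (lab in all_partitions(n)) {
    q <- 2 * sum(bv[lab[pi1] == lab[pi2]]) / (2 * m)
    if (q > best) { best <- q; best_lab <- lab }
  }
  list(Q = best, labels = best_lab)
}

# adjacency of c disconnected complete graphs of size k
disconnected_cliques <- function(k, c = 2) {
  n <- k * c
  A <- matrix(0, n, n)
  for (ci in seq_len(c)) {
    ix <- ((ci - 1) * k + 1):(ci * k)
    A[ix, ix] <- 1
  }
  diag(A) <- 0
  A
}

ring_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

chain_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

# pair-counting Rand index between two label vectors
rand_index <- function(a, b) {
  ut <- upper.tri(diag(length(a)))
  mean(outer(a, a, "==")[ut] == outer(b, b, "==")[ut])
}

# straight chain along x as a conformation
straight_chain <- function(n) {
  conformation(cbind(0:(n - 1), 0, 0), lattice = TRUE, bond_length = 1)
}

# small simulated FG map (annealed contacts, KR-balanced) for detection tests
make_fg_map <- function(N = 256, seed = 1, n_snapshots = 50, threshold = 3,
                        balanced = TRUE) {
  conf <- generate_cdp(N, seed = seed)
  snaps <- anneal_snapshots(conf, n_snapshots = n_snapshots, seed = seed + 1,
                            validate = FALSE)
  map <- contacts_from_snapshots(snaps, threshold = threshold)
  if (balanced) map <- kr_balance(map)
  attr(map, "conformation") <- conf
  map
}
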