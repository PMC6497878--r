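test_that("strengths follow row sums and the KR convention", {
  bal <- kr_balance(random_map(15, seed = 2))
  st <- strengths(bal)
  keep <- setdiff(1:15, bal$mask)
  expect_equal(st$k[keep], rep(1, length(keep)), tolerance = 1e-6)
  expect_equal(2 * st$m, length(keep), tolerance = 1e-5)

  tri <- contact_map(matrix(1, 3, 3) - diag(3))
  expect_equal(strengths(tri)$k, rep(2, 3))
  expect_equal(strengths(tri)$m, 3)

  map <- random_map(10, seed = 3)
  expect_equal(strengths(map)$k, rowSums(map$matrix))
})

test_that("the FG null is exactly normalized and matches a double-loop oracle", {
  for (seed in 1:5) {
    map <- random_map(30, seed = seed)
    st <- strengths(map)
    P <- null_matrix(map, null_model("fg", alpha = 1))
    expect_equal(sum(P), 2 * st$m, tolerance = 1e-9)
  }

  # alpha -> 0 recovers the NG shape (up to overall normalization)
  map <- random_map(12, seed = 6)
  P0 <- null_matrix(map, null_model("fg", alpha = 1e-12))
  png <- null_matrix(map, null_model("ng"))
  expect_equal(P0 / sum(P0), png / sum(png), tolerance = 1e-8)

  # 4-node chain map, alpha = 1, term-by-term against the brute-force sum
  A <- chain_graph(4)
  map4 <- contact_map(A)
  expect_equal(null_matrix(map4, null_model("fg", alpha = 1)),
               brute_fg_null(A, 1), tolerance = 1e-12)

  # masked bins carry no null weight
  mm <- random_map(10, seed = 7, mask = 4L)
  Pm <- null_matrix(mm, null_model("fg"))
  expect_equal(Pm[4, ], rep(0, 10))
  expect_equal(sum(Pm), 2 * strengths(mm)$m, tolerance = 1e-9)
})

test_that("modularity reproduces closed forms and brute-force sums", {
  for (seed in 1:5) {
    map <- random_map(25, seed = 10 + seed)
    one <- rep(1L, 25)
    for (g in c(0, 0.4, 1, 1.7))
      expect_equal(modularity_score(map, one, null_model("fg"), gamma = g),
                   1 - g, tolerance = 1e-12)
    expect_equal(modularity_score(map, 1:25, null_model("fg"), gamma = 0.7), 0)
  }

  # two 4-cliques joined by one edge, NG null, natural split
  A <- disconnected_cliques(4, 2)
  A[4, 5] <- A[5, 4] <- 1
  map <- contact_map(A)
  lab <- rep(1:2, each = 4)
  k <- rowSums(A)
  Png <- tcrossprod(k) / sum(k)
  diag(Png) <- 0
  expect_equal(modularity_score(map, lab, null_model("ng"), gamma = 1),
               brute_modularity(A, Png, lab, 1), tolerance = 1e-12)

  # label permutation invariance
  map <- random_map(20, seed = 31)
  lab <- sample(1:4, 20, replace = TRUE)
  q1 <- modularity_score(map, lab, null_model("fg"), gamma = 0.6)
  q2 <- modularity_score(map, c(3L, 1L, 4L, 2L)[lab], null_model("fg"),
                         gamma = 0.6)
  expect_equal(q1, q2, tolerance = 1e-14)
})

test_that("louvain recovers planted structure and obeys gamma limits", {
  # two disconnected 4-cliques: exact recovery at gamma = 1, NG null
  map <- contact_map(disconnected_cliques(4, 2))
  part <- louvain_communities(map, gamma = 1, null = null_model("ng"),
                              seed = 1, n_restarts = 3)
  expect_equal(part$n_communities, 2)
  expect_equal(rand_index(part$labels, rep(1:2, each = 4)), 1)

  # gamma = 0: nothing can beat the single community
  fgm <- make_fg_map(128, seed = 51, n_snapshots = 30)
  p0 <- louvain_communities(fgm, gamma = 0, seed = 1, n_restarts = 2)
  expect_equal(p0$n_communities, 1)

  # determinism per seed
  pa <- louvain_communities(fgm, gamma = 0.6, seed = 5, n_restarts = 2)
  pb <- louvain_communities(fgm, gamma = 0.6, seed = 5, n_restarts = 2)
  expect_identical(pa$labels, pb$labels)
  expect_identical(pa$Q, pb$Q)

  # larger gamma, smaller communities (single map, fixed seed)
  fgm2 <- make_fg_map(512, seed = 52, n_snapshots = 50)
  p04 <- louvain_communities(fgm2, gamma = 0.4, seed = 1, n_restarts = 2)
  p08 <- louvain_communities(fgm2, gamma = 0.8, seed = 1, n_restarts = 2)
  expect_gt(mean(p04$sizes), mean(p08$sizes))

  # empty graph propagates an error
  expect_error(louvain_communities(contact_map(matrix(0, 4, 4))),
               "empty graph|no off-diagonal")
})

test_that("gamma_scan matches direct calls and summarizes sizes", {
  fgm <- make_fg_map(128, seed = 61, n_snapshots = 30)
  sc <- gamma_scan(fgm, 0.6, seed = 3, n_restarts = 2)
  direct <- louvain_communities(fgm, gamma = 0.6, seed = 3, n_restarts = 2)
  expect_identical(sc[[1]]$labels, direct$labels)

  sc3 <- gamma_scan(fgm, c(0.4, 0.6, 0.8), seed = 3, n_restarts = 2)
  smry <- attr(sc3, "summary")
  expect_equal(nrow(smry), 3)
  expect_named(smry, c("gamma", "Q", "n_communities", "median_size",
                       "mean_size", "max_size"))

  expect_error(gamma_scan(contact_map(matrix(0, 4, 4)), c(0.4, 0.6)),
               "empty graph|no off-diagonal")
})
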