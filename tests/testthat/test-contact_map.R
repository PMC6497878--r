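test_that("contacts from a straight chain are forced by geometry", {
  conf <- straight_chain(5)
  map <- contacts_from_snapshots(list(conf), threshold = 3)
  expected <- outer(1:5, 1:5, function(i, j) as.numeric(abs(i - j) %in% 1:2))
  expect_equal(map$matrix, expected)
  expect_equal(diag(map$matrix), rep(0, 5))
  expect_true(isSymmetric(map$matrix))
})

test_that("contact counting matches a brute-force recount over snapshots", {
  conf <- generate_cdp(50, seed = 3)
  snaps <- anneal_snapshots(conf, n_snapshots = 8, seed = 4)
  map <- contacts_from_snapshots(snaps, threshold = 3)
  brute <- matrix(0, 50, 50)
  for (s in snaps) brute <- brute + (as.matrix(dist(s$coords)) < 3)
  diag(brute) <- 0
  expect_equal(unname(map$matrix), unname(brute))
  expect_true(all(map$matrix <= 8))

  short <- conformation(conf$coords[1:30, ], lattice = TRUE)
  expect_error(contacts_from_snapshots(list(conf, short)), "differ in length")
})

test_that("matrix text round-trips in both dialects and masks zero rows", {
  map <- random_map(12, seed = 5, mask = c(3L, 9L))
  for (fmt in c("dense", "sparse")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_contact_matrix(map, f, format = fmt)
    back <- read_contact_matrix(f)
    expect_equal(back$matrix, map$matrix, tolerance = 1e-12)
    expect_identical(back$mask, map$mask)
    expect_equal(back$bin_size, map$bin_size)
  }

  # a zero row in a headerless file is auto-masked with a report
  m <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  f <- withr::local_tempfile()
  writeLines(apply(m, 1, paste, collapse = " "), f)
  expect_message(back <- read_contact_matrix(f), "auto-masking")
  expect_identical(back$mask, 3L)

  # one-sided sparse triple is symmetrized
  f2 <- withr::local_tempfile()
  writeLines(c("# chromcomm contact_map: n=6 bin_size=1 format=sparse",
               "3\t5\t7.0", "0\t1\t2.0"), f2)
  suppressMessages(sym <- read_contact_matrix(f2))
  expect_equal(sym$matrix[4, 6], 7)
  expect_equal(sym$matrix[6, 4], 7)

  # malformed and asymmetric inputs are errors
  f3 <- withr::local_tempfile()
  writeLines(c("1 2", "3"), f3)
  expect_error(read_contact_matrix(f3, format = "dense"), "ragged|malformed")
  f4 <- withr::local_tempfile()
  writeLines(c("0 1 0", "2 0 1", "0 1 0"), f4)
  expect_error(read_contact_matrix(f4, format = "dense"), "asymmetric")
})

test_that("KR balancing reaches unit row sums and the Sinkhorn limit", {
  # already doubly stochastic: returned unchanged
  n <- 20
  ds <- contact_map(sinkhorn_oracle(random_map(n, seed = 1)$matrix))
  bal <- kr_balance(ds)
  expect_equal(bal$matrix, ds$matrix, tolerance = 1e-6)

  # 2x2 forced by row sums
  two <- kr_balance(contact_map(matrix(c(0, 0.37, 0.37, 0), 2, 2)))
  expect_equal(two$matrix, matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-8)

  # random symmetric positive vs independent Sinkhorn oracle
  map <- random_map(20, seed = 42)
  bal <- kr_balance(map)
  expect_true(bal$balanced)
  keep <- setdiff(seq_len(20), bal$mask)
  expect_lt(max(abs(rowSums(bal$matrix)[keep] - 1)), 1e-6)
  expect_lt(max(abs(bal$matrix - sinkhorn_oracle(map$matrix))), 1e-5)

  # masked (zero) rows stay zero and are reported in the mask
  m <- random_map(10, seed = 9)$matrix
  m[4, ] <- m[, 4] <- 0
  bal <- kr_balance(contact_map(m))
  expect_true(4L %in% bal$mask)
  expect_equal(bal$matrix[4, ], rep(0, 10))
  keep <- setdiff(1:10, bal$mask)
  expect_lt(max(abs(rowSums(bal$matrix)[keep] - 1)), 1e-6)
})

test_that("KR commutes with symmetric permutations", {
  map <- random_map(15, seed = 8)
  perm <- sample(15)
  bal <- kr_balance(map)
  bal_p <- kr_balance(contact_map(map$matrix[perm, perm]))
  expect_equal(bal_p$matrix[order(perm), order(perm)], bal$matrix,
               tolerance = 1e-6)
})

test_that("community structure is robust to the contact threshold", {
  conf <- generate_cdp(1024, seed = 31)
  parts <- lapply(c(2, 3, 4.5), function(th) {
    snaps <- anneal_snapshots(conf, 50, seed = 32, validate = FALSE)
    map <- kr_balance(contacts_from_snapshots(snaps, threshold = th))
    louvain_communities(map, gamma = 0.6, seed = 1, n_restarts = 2)
  })
  expect_true(all(vapply(parts, `[[`, integer(1), "n_communities") > 1))
  expect_gt(rand_index(parts[[1]]$labels, parts[[2]]$labels), 0.5)
  expect_gt(rand_index(parts[[2]]$labels, parts[[3]]$labels), 0.5)
})
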