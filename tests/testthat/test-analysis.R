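test_that("segment decomposition finds maximal runs and round-trips", {
  seg <- decompose_segments(c("A", "A", "B", "B", "B"))
  expect_equal(seg$start, c(1, 3))
  expect_equal(seg$end, c(2, 5))
  expect_equal(seg$community, c("A", "B"))

  # the alternation pattern: 5 segments, A and B non-contiguous
  seg <- decompose_segments(c("A", "B", "C", "A", "B"))
  expect_equal(nrow(seg), 5)
  expect_setequal(attr(seg, "non_contiguous"), c("A", "B"))

  # re-concatenation reproduces the labels exactly (random cases)
  for (seed in 1:10) {
    set.seed(seed)
    lab <- sample(1:4, 60, replace = TRUE)
    lab[sample(60, 5)] <- NA
    seg <- decompose_segments(lab)
    rebuilt <- rep(NA_integer_, 60)
    for (r in seq_len(nrow(seg)))
      rebuilt[seg$start[r]:seg$end[r]] <- seg$community[r]
    expect_identical(rebuilt, lab)
  }
})

test_that("borders exclude chain ends and mask-adjacent boundaries", {
  expect_equal(community_borders(c(1, 1, 2, 2, 1)), c(3, 5))
  expect_equal(community_borders(rep(1, 6)), integer())
  # boundary right after a masked stretch is not a border
  expect_equal(community_borders(c(1, 1, NA, 2, 2, 3)), 6)
})

test_that("end-to-end curves are exact on straight chains, per mode", {
  conf <- straight_chain(40)
  curve <- end_to_end_curve(conf)
  expect_equal(curve$mean_R, as.numeric(1:39))
  fit <- fit_scaling_exponent(curve, s_min = 2, s_max = 39)
  expect_equal(fit$exponent, 1, tolerance = 1e-12)

  # segment mode: one point per contiguous block, boundary monomers
  lab <- rep(1:2, each = 20)
  part <- structure(list(labels = lab), class = "partition")
  segc <- end_to_end_curve(conf, partitions = part, subchains = "segments")
  expect_equal(segc$s, 19)
  expect_equal(segc$mean_R, 19)
  expect_equal(segc$n, 2)
})

test_that("radius of gyration matches closed forms and the centered oracle", {
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1.5)
  expect_equal(radius_of_gyration(matrix(2, 7, 3)), 0)

  set.seed(4)
  pts <- matrix(rnorm(60), 20, 3)
  oracle <- sqrt(sum(sweep(pts, 2, colMeans(pts))^2) / 20)
  expect_equal(radius_of_gyration(pts), oracle, tolerance = 1e-12)

  curve <- data.frame(s = 1:3, mean_R = c(2, 4, 6), sem = c(.1, .1, .1))
  class(curve) <- c("scaling_curve", "data.frame")
  norm <- normalize_by_rg(curve, rg = 2)
  expect_equal(norm$mean_R, c(0.5, 1, 1.5))
})

test_that("asphericity separates spheres from lines and flags compact communities", {
  # collinear points
  expect_equal(asphericity(cbind(1:50, 2 * (1:50), 0)), 1, tolerance = 1e-12)

  # uniform points on a sphere surface
  set.seed(8)
  v <- matrix(rnorm(3000 * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  expect_lt(asphericity(v), 0.05)

  # FG community segments are more sphere-like than random subchains of
  # the same lengths (selection-matched control)
  fgm <- make_fg_map(512, seed = 21, n_snapshots = 50)
  conf <- attr(fgm, "conformation")
  part <- louvain_communities(fgm, gamma = 0.6, seed = 1, n_restarts = 2)
  seg <- decompose_segments(part)
  seg <- seg[seg$end - seg$start >= 9, ]
  a_seg <- mapply(function(a, b) asphericity(conf$coords[a:b, ]),
                  seg$start, seg$end)
  set.seed(99)
  a_rnd <- unlist(lapply(seq_len(nrow(seg)), function(k) {
    L <- seg$end[k] - seg$start[k] + 1
    vapply(1:10, function(j) {
      st <- sample(512 - L + 1, 1)
      asphericity(conf$coords[st:(st + L - 1), ])
    }, numeric(1))
  }))
  expect_lt(mean(a_seg), mean(a_rnd))
})

test_that("border overlap counts matches within the window", {
  lab <- rep(1:4, each = 10)
  part <- structure(list(labels = lab), class = "partition")
  own <- community_borders(part)
  expect_equal(border_overlap(part, own)$fraction, 1)
  expect_equal(border_overlap(part, integer())$fraction, 0)

  ov <- border_overlap(c(10, 20, 30), c(11, 29, 50), window = 1)
  expect_equal(ov$fraction, 2 / 3)
  expect_equal(ov$reciprocal, 2 / 3)
  expect_equal(ov$n_predicted, 3)

  # exact matching (window 0) is symmetric for equal-size sets
  a <- c(4, 9, 17)
  b <- c(4, 12, 17)
  expect_equal(border_overlap(a, b, window = 0)$fraction,
               border_overlap(b, a, window = 0)$fraction)
})

test_that("segments-per-community summaries follow the decomposition", {
  tc <- tads_per_community(c("A", "B", "C", "A", "B"))
  expect_equal(tc$n_communities, 3)
  expect_equal(tc$mean_segments, 5 / 3)

  expect_equal(tads_per_community(rep(1, 8))$mean_segments, 1)

  alt <- tads_per_community(rep(1:2, times = 12))
  expect_equal(alt$n_communities, 2)
  expect_equal(unname(as.numeric(alt$segments_per_community)), c(12, 12))
})

test_that("per-community signal summaries recover planted distributions", {
  lab <- rep(1:3, each = 60)
  expect_equal(signal_by_community(lab, rep(7, 180), min_size = 10)$median,
               rep(7, 3))

  # disjoint value ranges keep their ordering
  track <- c(runif(60, 0, 1), runif(60, 10, 11), runif(60, 100, 101))
  out <- signal_by_community(lab, track, min_size = 10)
  out <- out[order(out$community), ]
  expect_true(all(diff(out$median) > 0))
  expect_true(all(out$q1 <= out$median & out$median <= out$q3))

  # community-specific means recovered within sampling error
  set.seed(12)
  mu <- c(2, 5, 9)
  track <- rnorm(180, mean = mu[lab], sd = 0.5)
  out <- signal_by_community(lab, track, min_size = 50)
  out <- out[order(out$community), ]
  expect_equal(out$median, mu, tolerance = 0.2)

  # minimum-size filter
  lab2 <- c(rep(1, 60), rep(2, 10))
  expect_equal(nrow(signal_by_community(lab2, rnorm(70), min_size = 50)), 1)
})
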