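test_that("CDP growth yields self-avoiding unit-bond chains, reproducibly", {
  # shortest possible chain: two adjacent sites
  c2 <- generate_cdp(2, seed = 1)
  expect_equal(nrow(c2$coords), 2)
  expect_equal(sum(abs(c2$coords[2, ] - c2$coords[1, ])), 1)

  conf <- generate_cdp(512, seed = 7)
  expect_true(conf$lattice)
  expect_silent(check_conformation(conf))
  expect_equal(unique(bond_lengths <- sqrt(rowSums(diff(conf$coords)^2))), 1)

  # bit-reproducible per seed, different across seeds
  expect_identical(generate_cdp(128, seed = 3)$coords,
                   generate_cdp(128, seed = 3)$coords)
  expect_false(identical(generate_cdp(128, seed = 3)$coords,
                         generate_cdp(128, seed = 4)$coords))

  expect_error(generate_cdp(600, lattice_size = 8), "capacity")
})

test_that("the CDP bias compacts the walk relative to an unbiased SAW", {
  msee <- function(A, seeds) {
    mean(vapply(seeds, function(s) {
      co <- generate_cdp(512, A = A, seed = s)$coords
      sum((co[512, ] - co[1, ])^2)
    }, numeric(1)))
  }
  free <- msee(0, 7000 + 1:100)
  biased <- msee(1e4, 8000 + 1:100)
  expect_gt(free, 3 * biased)
})

test_that("small CDP ensembles already show the fractal-globule decay", {
  maps <- lapply(1:20, function(i) {
    conf <- generate_cdp(512, seed = 900 + i)
    snaps <- anneal_snapshots(conf, n_snapshots = 30, seed = 950 + i,
                              validate = FALSE)
    contact_probability(contacts_from_snapshots(snaps, 3), n_snapshots = 30)
  })
  p <- Reduce(`+`, lapply(maps, `[[`, "p")) / length(maps)
  # finite-size effects soften the decay at N=512 (~ -0.7 here, -0.9 at
  # N=4096); this is a smoke check, the full-scale band lives in the
  # acceptance suite
  fit <- fit_scaling_exponent(data.frame(s = maps[[1]]$s, p = p),
                              s_min = 8, s_max = 128, value = "p")
  expect_gt(fit$exponent, -1.2)
  expect_lt(fit$exponent, -0.55)
})

test_that("equilibrium globules stay confined and density limits are enforced", {
  conf <- generate_equilibrium_globule(256, seed = 5)
  r <- conf$params$radius
  expect_true(all(sqrt(rowSums(conf$coords^2)) <= r + 1e-9))
  expect_silent(check_conformation(conf))
  expect_identical(generate_equilibrium_globule(64, seed = 2)$coords,
                   generate_equilibrium_globule(64, seed = 2)$coords)

  tiny <- generate_equilibrium_globule(2, radius = 1, seed = 1)
  expect_equal(sum(abs(tiny$coords[2, ] - tiny$coords[1, ])), 1)

  expect_error(generate_equilibrium_globule(100, radius = 2), "density")
})

test_that("annealing preserves bonds, excluded volume and monomer order", {
  conf <- generate_cdp(200, seed = 11)

  # zero-move limit: output equals input
  still <- anneal_snapshots(conf, n_snapshots = 1, displacement_scale = 1e-9,
                            n_moves_per_snapshot = 10, seed = 1)
  expect_lt(max(abs(still[[1]]$coords - conf$coords)), 1e-6)

  snaps <- anneal_snapshots(conf, n_snapshots = 5,
                            n_moves_per_snapshot = 2000, seed = 2)
  for (s in snaps) {
    expect_lt(max(abs(sqrt(rowSums(diff(s$coords)^2)) - 1)), 1e-6)
    expect_false(is.finite(chromcomm:::cpp_min_pairdist(s$coords, 0.8)))
  }
  # order preserved: neighbours in index stay bonded neighbours in space
  expect_lt(max(abs(sqrt(rowSums(diff(snaps[[5]]$coords)^2)) - 1)), 1e-6)

  # reproducible per seed
  again <- anneal_snapshots(conf, n_snapshots = 5,
                            n_moves_per_snapshot = 2000, seed = 2)
  expect_identical(snaps[[5]]$coords, again[[5]]$coords)
})
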