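#' Generate a fractal globule by conformation-dependent polymerization
#'
#' Grows an on-lattice self-avoiding walk whose step selection is biased
#' toward sites in dense surroundings: an unoccupied candidate neighbour of
#' the head is weighted `1 + A * n`, where `n` is the number of occupied
#' lattice neighbours of the candidate, and an occupied candidate carries
#' weight `epsilon`; drawing an occupied candidate rejects the step, which
#' is then redrawn. With a large bias amplitude (`A = 1e4`) the growth is
#' space-filling and produces a fractal (crumpled) globule whose ensemble
#' contact probability decays approximately as `s^-1` with contour
#' separation `s` and whose end-to-end distance grows as `s^(1/3)`.
#'
#' A trapped head (all six neighbours occupied) backtracks up to
#' `backtrack` monomers; if the backtracking budget of a walk is exhausted
#' the walk restarts, up to `max_restarts` times, after which an error is
#' raised.
#'
#' @param N chain length (monomers), at least 2.
#' @param A bias amplitude (dimensionless, > 0 for fractal-globule growth;
#'   `A = 0` gives an unbiased self-avoiding walk).
#' @param epsilon weight of an occupied candidate site (0 < epsilon <= 1).
#' @param seed RNG seed; generation is bit-reproducible given the same seed
#'   and parameters.
#' @param lattice_size optional side of a cubic confinement lattice. The
#'   default (`NULL`) grows on an unbounded lattice: with a large `A` the
#'   globule compactifies by itself, so no box is needed. When given, the
#'   walk is confined to `lattice_size^3` sites and `N` must not exceed
#'   that capacity.
#' @param backtrack monomers removed per trapping event.
#' @param max_restarts restart cap before giving up.
#' @return an on-lattice [conformation()] with unit bonds.
#' @examples
#' conf <- generate_cdp(256, seed = 1)
#' radius_of_gyration(conf)  # compact: ~ (3 N / 4 pi)^(1/3) * sqrt(3/5)
#' @export
generate_cdp <- function(N, A = 1e4, epsilon = 1e-4, seed = 1,
                         lattice_size = NULL, backtrack = 10,
                         max_restarts = 100) {
  stopifnot(N >= 2, A >= 0, epsilon > 0, epsilon <= 1)
  L <- 0L
  if (!is.null(lattice_size)) {
    L <- as.integer(lattice_size)
    if (N > L^3)
      stop(sprintf("N = %d exceeds lattice capacity %d^3 = %d", N, L, L^3))
  }
  set.seed(seed)
  coords <- cpp_cdp_grow(as.integer(N), A, epsilon, L,
                         as.integer(backtrack), as.integer(max_restarts))
  restarts <- attr(coords, "restarts")
  attr(coords, "restarts") <- NULL
  conformation(coords, lattice = TRUE, bond_length = 1,
               params = list(model = "cdp", N = N, A = A, epsilon = epsilon,
                             seed = seed, restarts = restarts))
}

#' Generate an equilibrium globule (confined self-avoiding chain)
#'
#' A self-avoiding lattice chain confined to a sphere, equilibrated with a
#' mixture of slithering-snake (reptation) and kink-jump Monte Carlo moves.
#' At short contour separations the equilibrated chain shows near-ideal
#' end-to-end scaling `~ s^(1/2)`; beyond `s ~ N^(2/3)` the confinement
#' produces a plateau.
#'
#' @param N chain length (monomers).
#' @param radius confinement sphere radius in lattice units. The default
#'   (`NULL`) picks the smallest radius at which the sphere holds `N`
#'   monomers at the target lattice `packing_fraction`; see
#'   [eg_confinement_radius()] for sizing the sphere from a companion
#'   fractal globule's radius of gyration instead.
#' @param seed RNG seed.
#' @param packing_fraction target fraction of sphere lattice sites occupied
#'   by the chain when `radius` is `NULL` (default 0.5, a melt-like
#'   density).
#' @param n_moves Monte Carlo proposals for equilibration; default
#'   `max(2e5, 4 * N^2)`, enough for the slithering chain to renew its
#'   contour several times.
#' @param max_restarts restart cap for the initial chain placement.
#' @return an on-lattice [conformation()]; positions satisfy
#'   `||r_i|| <= radius` (sphere centered at the origin).
#' @export
generate_equilibrium_globule <- function(N, radius = NULL, seed = 1,
                                         packing_fraction = 0.5,
                                         n_moves = NULL,
                                         max_restarts = 200) {
  stopifnot(N >= 2)
  if (is.null(radius)) {
    radius <- max(1.8, (3 * N / (4 * pi * packing_fraction))^(1 / 3))
    while (cpp_sphere_capacity(radius) < N / packing_fraction)
      radius <- radius + 0.25
  }
  if (cpp_sphere_capacity(radius) < N)
    stop(sprintf(
      "density too high: sphere of radius %.2f holds %d lattice sites < N = %d",
      radius, cpp_sphere_capacity(radius), N))
  if (is.null(n_moves)) n_moves <- max(2e5, 4 * as.numeric(N)^2)
  set.seed(seed)
  coords <- cpp_eg_generate(as.integer(N), radius, n_moves,
                            as.integer(max_restarts))
  attr(coords, "restarts") <- NULL
  conformation(coords, lattice = TRUE, bond_length = 1,
               params = list(model = "eg", N = N, radius = radius,
                             seed = seed, n_moves = n_moves))
}

#' Confinement radius from a fractal globule's radius of gyration
#'
#' Helper translating the convention "confine the equilibrium globule in a
#' volume with the same diameter as the fractal globule's radius of
#' gyration" into a sphere radius. Both readings of that phrase are
#' supported: `"diameter_rg"` (sphere diameter equals R_g, the literal
#' reading) and `"diameter_2rg"` (sphere diameter equals 2 R_g, i.e. the
#' sphere radius equals R_g). Note that at matched chain length either
#' choice gives a site density above 1, which no lattice chain can reach;
#' [generate_equilibrium_globule()] raises an error in that case, and its
#' density-based default radius is the practical alternative.
#'
#' @param rg radius of gyration of the companion fractal globule.
#' @param interpretation which reading of the sizing rule to use.
#' @return sphere radius in lattice units.
#' @export
eg_confinement_radius <- function(rg,
                                  interpretation = c("diameter_rg",
                                                     "diameter_2rg")) {
  interpretation <- match.arg(interpretation)
  if (interpretation == "diameter_rg") rg / 2 else rg
}

#' Off-lattice randomization of a conformation by constrained annealing
#'
#' Randomly displaces monomers under two hard constraints: each bond keeps
#' its fixed length (displacements are projected onto the feasible circle
#' for interior monomers, sphere for chain ends) and no two monomers come
#' closer than the excluded-volume diameter (`ev_fraction * bond_length`).
#' Snapshots are taken every `n_moves_per_snapshot` proposals; registering
#' contacts over many snapshots of one on-lattice structure emulates an
#' ensemble of off-lattice variants.
#'
#' @param conf a [conformation()] (typically on-lattice).
#' @param n_snapshots number of randomized variants to return.
#' @param displacement_scale maximum random displacement per move proposal
#'   (lattice units) before projection onto the bond constraints.
#' @param n_moves_per_snapshot Monte Carlo proposals between snapshots;
#'   default one sweep (`N` proposals).
#' @param seed RNG seed.
#' @param ev_fraction excluded-volume diameter as a fraction of the bond
#'   length (default 0.8).
#' @param validate if `TRUE`, every emitted snapshot is checked against the
#'   bond and excluded-volume constraints and an error is raised on
#'   violation.
#' @return a list of off-lattice [conformation()] objects, monomer order
#'   unchanged.
#' @export
anneal_snapshots <- function(conf, n_snapshots = 1000,
                             displacement_scale = 0.5,
                             n_moves_per_snapshot = NULL, seed = 1,
                             ev_fraction = 0.8, validate = TRUE) {
  stopifnot(inherits(conf, "conformation"), n_snapshots >= 1,
            displacement_scale > 0)
  N <- n_monomers(conf)
  if (is.null(n_moves_per_snapshot)) n_moves_per_snapshot <- N
  ev <- ev_fraction * conf$bond_length
  set.seed(seed)
  mats <- cpp_anneal(conf$coords, as.integer(n_snapshots),
                     as.numeric(n_moves_per_snapshot), displacement_scale,
                     conf$bond_length, ev)
  out <- lapply(seq_along(mats), function(i) {
    snap <- conformation(mats[[i]], lattice = FALSE,
                         bond_length = conf$bond_length,
                         params = c(conf$params,
                                    list(anneal_seed = seed, snapshot = i)))
    if (validate) check_conformation(snap, tol = 1e-6, ev_diameter = ev)
    snap
  })
  out
}
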