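---
title: "Multiscale 3D communities in chromosome contact maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale 3D communities in chromosome contact maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcomm)
```

## The problem

Hi-C experiments measure, genome-wide, how often every pair of genomic loci
touches in 3D. Binned at a fixed resolution these measurements form a
symmetric contact matrix $A$, whose block structure encodes the chromosome's
spatial organisation: topologically associated domains (TADs) at the scale of
hundreds of kilobases, A/B compartments at the scale of whole chromosome
arms, and much in between. Most callers target one of these scales with a
dedicated algorithm. `chromcomm` instead treats the contact matrix as a
weighted network and detects *3D communities* — groups of bins with more
mutual contact than a polymer-aware null model expects — at any scale, moving
through scales with a single resolution parameter. A community does not have
to be one contiguous stretch of the chromosome: several genomically distant
segments may fold into one 3D object, and the method is deliberately allowed
to say so.

## Generalized modularity with a distance-decay null

Communities are found by maximizing the generalized modularity
$$
Q \;=\; \frac{1}{2m}\sum_{i \neq j}\bigl(A_{ij} - \gamma P_{ij}\bigr)\,
\delta(g_i, g_j),
$$
where $k_i = \sum_j A_{ij}$ is the strength of bin $i$, $m = \tfrac12\sum_i
k_i$, $g_i$ is the community of bin $i$, and $\gamma > 0$ is the resolution:
larger $\gamma$ penalizes grouping more strongly and yields smaller
communities. $Q$ lies in $[-1, 1]$; the diagonal is excluded throughout
(self-contacts are zeroed on construction of every contact map).

The null term $P_{ij}$ is what the observed contact weight is compared
against. The classical Newman–Girvan choice $P^{\mathrm{NG}}_{ij} = k_i
k_j/(2m)$ assumes any two bins may connect freely, which is wrong for
chromatin: a chromosome is a polymer, and the contact probability between two
loci falls off as a power law $|i-j|^{-\alpha}$ of their genomic separation,
with $\alpha \approx 1$ at the megabase scale — the signature of a compact,
largely unknotted *fractal (crumpled) globule*. The package's default null
builds this in:
$$
P^{\mathrm{FG}}_{ij} \;=\;
\frac{2m\, k_i k_j\, |i-j|^{-\alpha}}
     {\sum_{i' \neq j'} k_{i'} k_{j'}\, |i'-j'|^{-\alpha}},
\qquad \alpha = 1 \text{ by default.}
$$
The normalization makes $\sum_{i\neq j} P^{\mathrm{FG}}_{ij} = 2m$ exactly,
so the all-in-one-community partition always scores $Q = 1 - \gamma$ — a
useful algebraic anchor that the test suite checks at machine precision. With
the NG null the same identity holds only up to the excluded-diagonal term
$\sum_i k_i^2/(2m)$; NG is kept as a baseline, not as the default.

Two conventions matter and are fixed package-wide:

* genomic separations $|i-j|$ are always computed on *original* bin indices,
  never on indices compacted after removing unmappable bins — distance decay
  is physics, not an artifact of masking;
* masked bins carry zero strength, zero null weight, and the sentinel label
  `NA`; they are excluded from every sum and from border bookkeeping.

### The optimizer

`louvain_communities()` maximizes $Q$ by greedy local moving plus graph
aggregation (the Louvain scheme). Because $|i-j|$ is undefined between
aggregated super-nodes, $P^{\mathrm{FG}}$ is computed once at the finest
level and aggregated alongside $A$ (community-pair sums), which preserves the
objective exactly across levels. Determinism is engineered: the node sweep
order is a seeded shuffle each pass, ties in gain break toward the lowest
community id, a pass terminates when its summed $\Delta Q$ drops below
$10^{-10}$, and the best of `n_restarts` independently seeded runs wins (ties
keep the earliest seed). The returned partition is additionally guarded never
to score below the all-in-one or all-singleton partitions. On all graphs of
up to ten nodes in the test fixture family the optimizer is compared against
exhaustive enumeration over every set partition; it attains the optimum on
disconnected cliques and never exceeds it elsewhere (it cannot, but the
comparison also catches objective-function bugs).

Partitions at different $\gamma$ are computed independently — no nesting or
hierarchy is imposed, and none should be expected: the community spectrum is
a family of snapshots at different scales, not a tree.

Whether detection runs on balanced or raw counts is not dictated by the
method; the package defaults to Knight–Ruiz-balanced maps (the `--raw` CLI
flag and passing an unbalanced map override this), which makes all strengths
equal to one and lets $\gamma$ act purely on the distance structure.

## The fractal-globule simulator

The method's validation surface is a polymer model whose statistics are
known exactly in the scaling sense. `generate_cdp()` grows an on-lattice
self-avoiding walk by conformation-dependent polymerization: at each step,
every unoccupied neighbour of the head is weighted $1 + A\,n$, where $n$ is
the number of occupied lattice neighbours of that candidate *other than the
head itself* — i.e. its contacts with the rest of the chain — and occupied
candidates carry the small weight $\varepsilon$ (drawing one rejects the
step, which is redrawn). With the default $A = 10^4$ and $\varepsilon =
10^{-4}$, stepping into open space (weight 1) is four orders of magnitude
less attractive than hugging the existing globule (weight $\sim A$), and the
growth is space-filling.

The clause "other than the head itself" is the one place the growth rule had
to be pinned down beyond its usual one-line description. Counting the head
makes every candidate's weight $\approx A\,n$ with $n \geq 1$, so the bias
between candidates is only linear in $n$ and the walk stays nearly ideal
(measured at $N = 4096$: $R_g \approx 31$, contact-decay exponent $-1.6$,
end-to-end exponent $0.50$). Excluding it restores the intended
surface-adhesion bias and reproduces the fractal-globule contract the model
exists for: $R_g \approx 9$, contact probability $P(s) \sim s^{-1}$
(measured $-0.90 \pm 0.02$ over $s \in [8, 512]$) and end-to-end distance
$R(s) \sim s^{1/3}$ (measured $0.35$). Growth proceeds on an unbounded
lattice — the bias alone compactifies the walk — with an optional cubic
confinement box whose capacity is checked. A trapped head (all six
neighbours occupied) backtracks up to ten monomers and regrows; a walk that
exhausts its backtracking budget restarts from scratch (at $N = 4096$
restarts are rare).

`anneal_snapshots()` turns one on-lattice structure into an ensemble of
off-lattice variants: monomers are displaced by random proposals (maximum
displacement 0.5 lattice units) projected back onto the exact bond-length
constraint — onto the circle at distance 1 from both chain neighbours for
interior monomers, onto the unit sphere around the single neighbour for chain
ends — and rejected if any pairwise distance would fall below the
excluded-volume diameter of $0.8 \times$ bond length (any value below the
bond length preserves self-avoidance; 0.8 is fixed for reproducibility).
Interior monomers whose neighbours are collinear have a degenerate feasible
circle and simply do not move that sweep. One sweep of $N$ proposals
separates consecutive snapshots by default.

`contacts_from_snapshots()` counts, for every pair, the snapshots in which
the two monomers lie within three lattice spacings (strict inequality). The
threshold is deliberately coarse; the community structure found downstream is
insensitive to varying it by $\pm 50\%$ at desk scale ($N = 1024$: 7/4/3
communities at thresholds 2/3/4.5, pairwise Rand index 0.69/0.91 — checked in
the suite). Contact maps are then balanced with Knight–Ruiz before
detection, exactly as Hi-C maps are.

### The equilibrium-globule reference

The comparison polymer is a self-avoiding chain confined to a sphere,
equilibrated by a 80/20 mix of slithering-snake (reptation) and kink-jump
moves — `generate_equilibrium_globule()`. Its known statistics are ideal-chain
scaling $R(s) \sim s^{1/2}$ at short range and a confinement plateau
$R(s) \sim s^0$ at long range.

Sizing the confinement needed a decision. The literal convention "a volume
with the same diameter as the fractal globule's radius of gyration" is
geometrically infeasible at matched chain length: at $N = 4096$ the FG's
$R_g \approx 9.2$, and a sphere of diameter $R_g$ (or even $2R_g$) holds far
fewer than 4096 lattice sites, so no self-avoiding chain fits.
`eg_confinement_radius()` exposes both literal readings for users who want
them at other densities, and the generator raises the density error in the
infeasible cases. The default instead fixes the lattice packing fraction at
0.5 — a melt-like density — which gives the EG the same overall size
($R_g \approx 9.4$) as the companion FG ($R_g \approx 9.2$): the evident
intent of the sizing rule. Equilibration runs $4N^2$ proposals by default,
enough for the slithering chain to renew its contour several times.

### Where the ideal-chain window ends

A confined melt chain cannot show $s^{1/2}$ all the way to $s = N^{2/3}$:
the regime ends at the geometric crossover $s^*$ where $R(s^*)$ reaches the
confinement size, $s^* \approx (R_\infty/b_{\mathrm{eff}})^2 \approx 100$–$120$
here, and the bend around $s^*$ is broad. Fitting across the bend would
report an exponent pulled far below $\tfrac12$ at any feasible density
(measured $0.24$–$0.41$ over $[8, 256]$ for packing fractions 0.5 down to
0.13 — dilute spheres also start to show self-avoiding-walk swelling at
short range, which is why lowering the density does not rescue a wide
window). The package therefore fits the ideal regime over $s \in [8, 64]$,
below the crossover, and verifies the plateau separately
($|$slope$| < 0.15$ for $s > N^{2/3}$). The FG window is $s \in
[8, N^{2/3}]$ as usual — the fractal globule has no confinement crossover,
only finite-size deviations at large $s$ which that cap avoids.

## Community compactness, and what the EG comparison can show

For every partition, `decompose_segments()` splits the chain into maximal
single-community runs; each contiguous segment of length $s$ (in bonds)
contributes the distance between its two boundary monomers to the
community-level $R(s)$ curve, compared against the all-subchain curve at
matched $s$ (log-binned, segment-count weighted). In fractal globules the
community segments sit systematically below the all-subchain curve, with a
deficit that grows with $s$ (17% in the smallest bins to ~50% in the
largest): communities are compact, loop-like substructures.

In equilibrium globules the published expectation is that the two curves
carry *the same scaling*. That is what the acceptance suite asserts (segment
and all-subchain exponents within 0.07, and a median deficit smaller than
the FG's). It deliberately does not assert a zero deficit: because contacts
are registered over annealed variants of a single conformation, detection
selects 3D-proximal subchains even in the EG, leaving its segments a
few-to-fifteen percent short of the all-subchain curve — invisible on
logarithmic axes, but nonzero. A scientist comparing the curves would call
them coincident; a bin-counting test would not, and the distinction is the
selection effect, not the polymer physics.

A related selection subtlety affects asphericity. Communities are *more
sphere-like than random subchains of the same length* (gyration-tensor
asphericity 0.46 vs 0.53 in FG at desk scale), which is the selection-matched
version of the claim that communities are compact, sphere-like objects. They
are *not* more spherical than the whole globule — the globule itself is
nearly spherical (asphericity $\approx 0.26$ at $N = 512$) — so the suite
tests the matched comparison.

## Knight–Ruiz balancing

`kr_balance()` implements the Knight–Ruiz inner–outer Newton iteration
(conjugate-gradient inner solves with the standard step-length safeguards)
to find the positive diagonal $D$ with $DAD$ doubly stochastic; unmasked row
and column sums land within $10^{-6}$ of one. Rows that sum to zero are
masked first; masked bins are removed before balancing and re-inserted as
zero rows afterwards; the diagonal is zeroed before balancing (the
modularity sum never sees it, and balancing with self-contacts would leak
weight into a term the objective ignores). The independent check in the test
suite is a plain Sinkhorn–Knopp alternating-scaling oracle, with agreement
required to $10^{-5}$, plus invariance of the result under symmetric
permutation.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `gamma` | 0.6 | — | resolution; larger = smaller communities |
| `alpha` | 1 | — | null-model decay exponent; ~1 for Hi-C at 100 kbp |
| `A` | $10^4$ | — | CDP bias amplitude; 0 gives an unbiased SAW |
| `epsilon` | $10^{-4}$ | — | weight of stepping toward an occupied site |
| `threshold` | 3 | lattice units | contact distance |
| `n_snapshots` | 1000 | — | annealed variants registered per structure |
| `displacement_scale` | 0.5 | lattice units | max proposal displacement |
| `packing_fraction` | 0.5 | — | EG lattice occupancy inside the sphere |
| `n_restarts` | 10 | — | Louvain restarts |
| `window` | 1 | bins | border-overlap matching tolerance |
| `min_size` | 50 | bins | smallest community in signal summaries |

The border-overlap window of $\pm 1$ bin (100 kbp at typical Hi-C
resolution) is a choice, not a published constant; it is exposed because
reasonable analyses may want 0 or 2.

## What the simulations do and do not establish

The simulator provides ground truth for exactly the properties the method
claims to exploit: the $s^{-1}$ contact decay that motivates the null, the
$s^{1/3}$ vs $s^{1/2}$ end-to-end contrast between fractal and equilibrium
globules, and the compactness of detected communities. Passing these tests
shows the machinery is self-consistent at the polymer level. It does not
show that any particular biological claim transfers: simulated globules have
no loop extrusion, no CTCF grammar, no replication timing structure, uniform
mappability (no masked bins unless injected), and a single chain rather than
a nucleus of territories. Analyses of real Hi-C maps (border overlap with
reference TAD calls, CTCF coincidence, per-community expression summaries)
are implemented and tested against constructed fixtures, but their published
numbers depend on external datasets and are not reproduced here.

Problem sizes used by the automated suite, chosen to make the scaling
regimes legible while keeping runs desk-scale: ensembles of 20 globules of
$N = 4096$ monomers with 100 annealed snapshots each for the scaling and
compactness checks (the published simulations used 200 realizations and
$10^3$ snapshots; the wider ensemble narrows error bars but does not move
the fitted exponents, which are already stable at 20 chains), $N = 512$–$1024$
for detection property tests, and 200-bin random matrices for balancing.

## Known limitations

* The Louvain optimizer is greedy; on adversarial graphs it can stop in
  local optima (the restart mechanism and the trivial-partition guard bound
  the damage, and the exhaustive oracle bounds it on small graphs).
* $P^{\mathrm{FG}}$ is dense, so memory scales as the square of the number
  of bins; whole-chromosome maps at 100 kbp (a few thousand bins) are
  comfortable, 10 kbp whole-genome maps are not the target.
* The FG null assumes a single power law. Real chromosomes show
  scale-dependent decay exponents; `alpha` is exposed, but a broken
  power-law null is future work.
* On-lattice generation plus constrained annealing is a fast emulation of an
  off-lattice ensemble, not molecular dynamics; topological moves (strand
  crossing) never occur, which is precisely what preserves the fractal
  globule's unknotted state but also means annealing explores conformations
  near the grown structure only.
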