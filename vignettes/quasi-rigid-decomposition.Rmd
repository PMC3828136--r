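---
title: "Quasi-rigid domain decomposition of viral capsids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-rigid domain decomposition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the elastic
model and its assumptions, the strain functional and its minimizer,
the order parameters, the synthetic assemblies used for validation,
and the numerical choices that a maintainer would want spelled out.

## The elastic model

The capsid is treated as a harmonic solid around its crystal
structure: the free energy is the quadratic form
$F = \tfrac12\,\delta x^\top M\,\delta x$ over displacements of the
$N$ main-chain centroids. Springs of uniform strength connect every
pair of interaction centres within a cutoff. Two centres represent
each residue — the CA atom for the main chain and the unweighted
centroid of the side-chain heavy atoms read from the file (absent for
glycine and for residues whose side-chain atoms are unresolved).
Using observed atoms avoids a geometric reconstruction rule for side
chains; the price is that missing side-chain density silently demotes
a residue to a single centre, which is the right behaviour for
low-resolution capsid structures.

Side-chain coordinates never appear downstream: they are eliminated
analytically. `effective_mainchain_matrix()` forms the full
two-centroid Hessian and returns the Schur complement after solving
out the side-chain block with a sparse Cholesky factorization, so the
operator stays $3N \times 3N$ and keeps the six global rigid motions
in its null space exactly (translations) or to $10^{-8}$ (linearized
rotations). A side-chain centre with too few independent couplings
makes the side block singular; this is reported by residue rather
than regularized away, because it indicates a cutoff far below the
structure's contact scale.

Assumptions worth stating:

* **Empty shells.** The model is built from the protein shell alone.
  The harmonic approximation guarantees the model's stability by
  construction, which stands in for the stabilising genome and
  protein–nucleic-acid contacts that crystal structures usually do
  not resolve. Conclusions about assembly units obtained this way are
  necessarily tentative where genome interactions dominate.
* **Uniform springs.** All spring constants are 1 in arbitrary
  energy/Å² units. Every quantity used for a decision — strain
  ratios, integrity, tile types, captured fraction — is invariant
  under a global stiffness rescaling (the tests assert that doubling
  all springs doubles every eigenvalue), so thermal prefactors are
  absorbed into the units.

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 7.5 | Å | established two-centre interaction range; rebuilt networks are sensitive mostly through connectivity, and the value is exposed because reasonable conventions differ by ±1 Å |
| decimated cutoff | 15 | Å | one centroid per two residues doubles the spacing, so the range is rescaled accordingly |
| `backbone_bonus` | 1 | — | consecutive main-chain centroids are always coupled; whether they deserve extra stiffness is a modelling convention, so the multiplier is exposed and defaults to "no special treatment" |
| `spring` | 1 | energy/Å² | see uniform-spring note above |
| null tolerance | 1e-8 × largest computed eigenvalue | — | separates the six rigid-motion modes (numerically ~1e-12 relative) from genuinely soft modes even at stiffness contrast 100 |
| retained modes `M` | all capsid modes below the 5th nonzero eigenvalue of one coat protein, floor 10 | — | keeps every mode softer than the first internal deformations of a single protein; the floor guards the pathological case of a reference protein softer than the assembly |
| mode cap `n_modes` | 100 | — | the low-energy band that drives domain motion; raising it changes strains by $O(1/\lambda)$ tails only |

The reference protein for the `M` rule is the first protein of the
structure by default and is configurable, because assemblies of
quasi-equivalent conformers (T = 3 shells) do not say which conformer
is "the" coat protein; the choice moves the threshold by the spread
of the conformers' 5th eigenvalues, which is small for structurally
identical chains.

## The strain functional and its minimizer

For residues $i, j$ with native separation direction
$\hat d_{ij}$ and mode displacements $v_{l,i}$,

$$ s_{ij} \;=\; \sum_{l=1}^{M} \frac{1}{\lambda_l}
   \left[ \hat d_{ij} \cdot (v_{l,i} - v_{l,j}) \right]^2 . $$

$s_{ij}$ is zero exactly when the pair co-moves rigidly in every
retained mode — including rigid rotations, for which the relative
displacement is perpendicular to the separation. The objective at
fixed $Q$ is the sum of $s_{ij}$ over all intra-domain pairs; domains
are not constrained to be connected in sequence or compact in space.

The minimizer is a stochastic greedy search from a uniform-random
labelling: move a random residue to a random other domain, accept
only strict decreases (ties rejected, to prevent label drift), never
empty a domain, and stop when consecutive rejections reach the
residue count. Because that stopping rule is itself stochastic, the
implementation follows it with deterministic best-move sweeps until
no single-residue move improves the objective; the returned partition
is therefore always 1-move locally optimal, and the accepted-move
strain trace (kept in `$trace`) is strictly decreasing. Move
evaluation is incremental — a move touches only the residue's strain
rows against its old and new domains — and the tests assert the
incremental total equals a full recomputation.

Split/join refinement counters asymmetric local minima: while some
domain's strain exceeds the mean by more than `outlier_k` (default 2)
standard deviations, the two lowest-strain domains are merged, the
highest-strain one is split by the plane through its centroid normal
to its principal spatial axis, and the greedy pass is rerun. The
outlier multiple and the bisection rule are design choices (the
heterogeneity test only needs *a* split that preserves $Q$); PCA
bisection was chosen because it is deterministic and roughly halves
the domain regardless of its shape. `sweep_partitions()` runs
`restarts` (default 5) independent chains per $Q$ with seeds derived
from a mandatory master seed, so every reported partition is
reproducible.

By default all residue pairs enter the objective. For very large
shells a `pair_cutoff` restricts sums to pairs within a native
distance; the result is then explicitly flagged as an approximation
in the field and the report, since distant pairs do carry strain when
domains are large.

## Rigid projection

Each retained mode splits orthogonally into per-domain rigid motion
plus internal fluctuation. The rigid subspace of a domain is spanned
by its three translations and three rotations linearized about its
unweighted centroid — centroid anchoring keeps translations and
rotations nearly orthogonal before orthonormalization — and a
rank-revealing SVD with tolerance $10^{-10}$ drops degenerate
directions (collinear domains have rank 5, singletons 3). Weights
are uniform per residue, consistent with the massless uniform
network. The captured fraction

$$ f \;=\; \frac{\sum_l \lVert P v_l \rVert^2 / \lambda_l}
               {\sum_l 1/\lambda_l} $$

is 0 up to numerics when the whole capsid is one domain (modes are
orthogonal to global rigid motions) and exactly 1 for all-singleton
partitions; splitting any domain can only grow the projected
subspace, so $f$ is monotone under refinement.

## Selection order parameters

* **Integrity**: per protein, the largest fraction of its residues in
  one domain; averaged *unweighted* over proteins, so short chains
  count as much as long ones. When a structure defines subdomain
  ranges, the same score over subdomains exposes mechanical units
  that recombine parts of different proteins.
* **Tile types**: single-linkage clustering of domain sizes with a
  band of 3% of the mean domain size at that $Q$. Size is a proxy
  for structural equivalence — cheap, orientation-free, and exactly
  what breaks when a subdivision fragments arbitrarily. The
  mean-of-all-domains reference (rather than per-pair) makes the band
  a single number per $Q$; both interpretations agree on monodisperse
  and clearly bimodal size sets.
* **Interlocking**: for each protein, how many of its first and last
  20 residues live outside its dominant domain; termini are averaged
  separately over proteins and the larger average is returned. For
  proteins shorter than 40 residues the terminal window is clipped to
  half the length (logged). Zero interlocking together with an
  integrity peak marks units that are candidates for *assembly*
  blocks, not merely mechanical ones.
* **`select_optimal()`** returns interior integrity peaks with at
  most `max_types` (default 3) tile types, ranked by integrity and
  then by larger $Q$ — the smallest viable units. Endpoint maxima are
  not candidates (a monotone profile has no interior peak). The
  ranking is advisory by design: the final call on a real capsid also
  uses visual inspection of the domain shapes, so the full profiles
  are always retained.

## Synthetic assemblies

The toys plant the ground truth the method is supposed to find:
stiff springs within blocks, soft couplings between them, with block
membership doubling as the "protein" bookkeeping.

* `make_hinge_toy()`: two stiff triangles coupled softly. The soft
  coupling is distributed over all nine cross-triangle pairs rather
  than a single hinge spring: one spring between two rigid bodies
  leaves five zero-energy mechanisms that would contaminate the
  rigid-motion null space, whereas the distributed coupling keeps
  exactly six null modes while the lowest modes remain hinge-like
  relative motions of the triangles.
* `make_ring_assembly(K, n)`: K jittered clusters on a circle, soft
  couplings between ring neighbours. Its minimized-strain profile
  reproduces the kink phenomenology at the planted $Q = K$.
* `make_icosahedral_toy()`: one random cluster replicated by the 60
  rotations of the icosahedral group (generated by closure of a
  5-fold and a 3-fold generator), soft couplings between units whose
  centroids fall within 1.1× the connectivity threshold of the
  unit-adjacency graph. With `fuse = "trimer"` the couplings inside
  each triple of units around a 3-fold axis (the cosets of the 3-fold
  subgroup) are stiffened to the intra-unit value, so the planted
  blocks — and the toy's proteins — become the 20 trimers: the
  integrity profile then peaks *interior* at $Q = 20$, emulating the
  situation where 60 chemically identical chains assemble via 20
  trimeric capsomeres.

Default sizes — 8 points per ring block, 4 per icosahedral unit,
stiffness contrast 100, jitter from uniform sampling in a ball —
were chosen once as the smallest systems whose soft and stiff
spectral bands are cleanly separated; at contrast 100 the planted
partitions capture >99% of the motion, which is the $f \to 1$ limit
the tests check.

What the toys deliberately do **not** emulate: side chains (toys are
single-centre), realistic protein geometry and packing density,
quasi-equivalent conformers, sequence-swapped arms, and genome
contacts. Passing the planted-recovery tests therefore shows the
machinery is correct — eigensolver, strain, minimizer, order
parameters — not that any particular real capsid will show an
equally clean integrity peak; real profiles are noisier and their
selection step intentionally keeps a human in the loop.

## Numerical choices

* **Eigensolver.** Dense symmetric diagonalization up to 1000
  degrees of freedom, shift-invert Arnoldi above: ARPACK is run on
  $(M + \sigma I)^{-1}$ with $\sigma = 10^{-4}\,\overline{M_{ii}}$
  through a sparse Cholesky factor, which maps the smallest
  eigenvalues to the dominant end of the spectrum where Arnoldi
  converges fast. Ritz vectors are re-orthonormalized and signs are
  fixed (largest-magnitude component positive) so results are
  deterministic up to degeneracies. Icosahedral symmetry makes
  degenerate clusters ubiquitous; tests compare eigenvectors only at
  spectrally isolated modes and compare subspace quantities
  otherwise.
* **Degenerate splits.** If PCA bisection of a domain puts all
  residues on one side (coincident projections), the split falls back
  to the median and then to an index split, so refinement always
  preserves $Q$.
* **Ties.** Zero-gain moves are rejected everywhere; on exactly
  degenerate landscapes (e.g. partitioning a rigid trimer interior)
  the initial random labels persist, which is what makes
  over-partitioned $Q$ values score low integrity and many tile
  types — the signal the selection step uses.
* **Problem sizes.** The shipped tests and the acceptance script run
  the hinge (6 points), a 32-point ring, 9-point enumeration oracles
  (all $3^9$ labellings), a 100-point ring for the sparse/dense
  cross-check, and 240-point icosahedral toys with sweeps over
  targeted $Q$ grids; these sizes keep full sweeps in seconds while
  every band of the physics (null, soft, stiff) stays resolved.

## Known limitations

* mmCIF files are read but their assembly operators are not expanded;
  supply pre-expanded assemblies (the VIPERdb dialect) or PDB files
  with REMARK 350.
* Tile typing is by size only; two domains of equal size but
  different architecture count as one type, as a size-based proxy
  must.
* No symmetry-adapted eigensolver: the full sparse problem is solved
  directly, which is the practical bound on capsid size (order $10^5$
  residues with the decimated backend).
* The greedy minimizer guarantees local, not global, optima;
  restarts plus split/join make planted optima reliable at desk
  scale, but on rough landscapes (large $Q$, weak contrast) the
  reported strain is an upper bound.
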