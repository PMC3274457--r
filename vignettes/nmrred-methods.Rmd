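---
title: "Methods: restraint redundancy, barrel geometry and trajectory metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restraint redundancy, barrel geometry and trajectory metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrred)
```

This vignette records the mathematical conventions and solver choices
behind `nmrred`, in enough detail to reproduce every number the package
computes.

## 1. Restraints and bound matrices

An NOE restraint is a pair of atom selections with distance bounds
`[l, u]` in Ångström. The CNS/X-PLOR dialect writes
`assign (selA)(selB) d dminus dplus`, which `parse_mr()` converts with
the standard convention `l = d - dminus`, `u = d + dplus` (negative
lowers clamp to 0 with a warning). Pseudoatom selections ending in `#`
(groups of equivalent hydrogens) are kept as single nodes; when
coordinates are needed they resolve to the centroid of the matching
atoms.

`build_bounds()` places the restraints on a **node universe** — one
node per distinct `(residue, atom-name)` selection — on top of one of
three baselines:

* `restraints_only`: every pair starts at `[0, u_max]`
  (`u_max = 100` Å by default, larger than any SH3-domain dimension, so
  every pair uncertainty is finite);
* `chain_model`: sequence-adjacent nodes additionally get the
  sequential upper bound `u` (5 Å by default), so smoothing yields
  `u_ij = u·|i − j|` capped at `u_max`;
* `topology`: node pairs within the same or sequentially adjacent
  residues get near-exact bounds (width 0.02 Å) around their distance
  in a reference structure. Restrained nodes are almost always
  hydrogens that are never covalently bonded *to each other*, so "the
  geometry fixed by the covalent structure" is expressed through these
  same-/adjacent-residue pairs rather than through literal bond
  lengths.

All applicable sources are intersected per pair (tightest lower,
tightest upper); an empty intersection is reported as an inconsistency
naming the offending pair.

### Triangle smoothing

`smooth_bounds()` tightens the matrices with the triangle inequality:
upper bounds become all-pairs shortest paths over the upper-bound graph
(Floyd–Warshall), and lower bounds are raised by iterating the inverse
triangle inequality `l_ij ≥ max_k(l_ik − u_kj, l_kj − u_ik)` to a fixed
point. The kernel is compiled (Rcpp) because redundancy ranking runs it
once per leave-one-out subset. Smoothing is idempotent and never
loosens a bound. **Tetrangle (four-point) smoothing is not performed**:
bounds are valid but not always the tightest geometrically realisable
ones. `path_oracle()` is an independent, exhaustive re-implementation
(branch-and-bound over simple paths; plain-R fixed point) used by the
test suite to verify the kernel on every random instance it is given.

## 2. Unique information

The uncertainty of a pair bounded to `[l, u]` is the entropy of the
uniform distribution on the interval, `log2(u − l)` bits, and the
structure uncertainty of a smoothed matrix is the per-node average
`H = (1/N) Σ_pairs log2(u_ij − l_ij)` over all unordered pairs, skipping
pairs fixed to width < 10⁻⁶ Å (their log diverges; they carry no
residual uncertainty).

The **unique information** of restraint `r` is the increase in
structure uncertainty caused by removing it: the set with and without
`r` are built over the *same* node universe, smoothed, and their
per-pair uncertainties differenced.

A convention choice matters here. Removing a restraint always widens
its *own* pair at least a little — even in a fully triangulated set,
the tightest two-hop path through other points is generically looser
than the direct bound — so differencing over *all* pairs can never be
exactly zero, and "fully redundant" sets would not rank as such. The
package therefore differences, by default, over the pairs **other
than** the removed restraint's own pair: the information the restraint
propagates to the rest of the structure through the triangle
inequalities. Under this convention:

* every restraint of a rigid, fully restrained pentahedron has
  `I_uni = 0` exactly;
* every restraint of a fully triangulated point cloud (all pairs
  restrained with common bounds) has `I_uni = 0` exactly;
* `I_uni ≥ 0` always, because adding a restraint can only tighten
  every other pair.

The literal all-pairs difference remains available via
`include_removed_pair = TRUE`. `rank_restraints()` records the
convention, the log base and the per-node normalisation as attributes
of its result, and `make_reduced_set()` / `make_random_set()` consume
that ranking (the random variant samples only from the low-information
window, 0–0.01 bits by default, under an isolated seed).

## 3. Contact order and its information-weighted analogue

`contact_order()` is `CO = (1/(N_c·N_s)) Σ_contacts |k − l|` over a
`contact_map()` (representative-atom Cβ rule — Cα for glycine — or
minimum heavy-atom distance; strict threshold; minimum sequence
separation 2). `co_star()` replaces each contact's sequence separation
with `base^{I_uni}/u`. Under the sequential chain model the smoothed
width of a pair with no direct restraint is exactly `u·|k − l|`, so the
model's closed-form information (`chain_information()`, restraint-level
and unnormalised) is `log2(u·|k − l|)` and `co_star()` collapses to
`contact_order()` identically — the consistency test the acceptance
suite runs on random structures.

## 4. Barrel cavity geometry

`main_axis()` fits the axis of a β-barrel as the line maximising the
minimal distance from the backbone points to the line (the widest empty
cylinder through the point cloud). The max–min objective is
non-smooth, so the solver anneals a soft minimum
`−(1/β)·log Σ exp(−β·d_i)` over β ∈ {1, 4, 16, 64, 256} with
Nelder–Mead, multistarting from the three principal axes plus seeded
perturbations; the on-axis point is kept within half a radius of
gyration of the centroid to fix the translation degeneracy.

`slab_profile()` slides a slab (width 2 Å, step 0.5 Å) along the axis;
each slab's points are projected onto the plane perpendicular to the
axis and the inner cavity radius is the radius of the **largest empty
circle** with centre constrained to the convex hull of the projected
points. That solver is exact by candidate enumeration: the optimum of
this generalised 1-centre problem is either a vertex of the hull
constraint, equidistant from three points (a circumcenter), or
equidistant from two points on a hull edge (bisector–edge crossing);
all candidates are enumerated and the best feasible one returned. The
test suite stress-tests it against 10⁴ random candidates per instance.

A slab of width `w` over a barrel whose planted radius varies as `r(z)`
reports `min over the slab of r(z)`, not `r(center)` — the profile a
cavity of that shape truly has. Recovery tests therefore compare
against the per-slab minimum of the planted law. For such recovery
studies the barrel fixture offers a ring arrangement
(`fix_ideal_barrel(..., arrangement = "rings")`): full uniform rings at
cell-centred z-levels pin the empty-circle centre to the axis, whereas
a spiral's z–angle coupling leaves angular gaps among the narrowest
points and biases slab radii upward. `barrel_length()` is the axial
extent of the non-empty slabs. Limitations: one straight axis, slabs
perpendicular to it; curved barrels are out of scope.

## 5. Trajectory metrics

`superpose()` is a standard Kabsch fit (SVD with determinant
correction) returning the rotation, translation and fitted RMSD.
`drift_series()` regresses the per-frame superposed RMSD on time
(Å/ns) and reports the OLS slope with its 95% CI.

The toy-trajectory generator plants drift as a per-atom displacement
field **projected orthogonal to the six rigid-body modes** of the
selection and normalised to unit RMS. This keeps the optimal Kabsch
rotation exactly the identity, so the fitted RMSD at time `t` (ns) is
exactly `|a·t + b + ε_t|` with planted slope `a`, intercept `b` and
amplitude noise `ε`. Two statistical points follow:

* a *rigid* frame motion plus noise cannot produce a drift slope —
  superposition removes it — which is why the generator plants an
  internal deformation mode instead;
* when the amplitude crosses zero, the absolute value folds the noise
  and biases OLS, so slope-recovery studies use a positive baseline
  offset (`drift_intercept`) and measure RMSD against the underlying
  structure (`drift_series(reference = )`), keeping the linear model
  correctly specified. Under that design the planted slope falls inside
  its 95% CI at the nominal rate.

Region centre-of-mass distances use the SH3-loop presets (RT loop
8–23, n-src loop 30–37, distal hairpin 41–47) or arbitrary named
ranges; `hydrophobic_core_pairs()` carries the five side-chain carbon
monitor pairs around the core. `contact_probability()` is
`Φ((threshold − mean)/sd)` under the Gaussian model (or a frame count
under the empirical one), and `hbond_series()` flags a bond as formed
when the *mean* donor-H–acceptor distance is below 2.5 Å.

## 6. Water-bridge networks

`donors_acceptors()` flags donor hydrogens and acceptor heavy atoms per
residue from fixed templates (backbone O/OXT and amide H except
proline; side-chain templates for all 20 standard residues). A water
bridges residues `p ≠ q` in a frame when one of its atoms is strictly
within 2.5 Å of a flagged atom of `p` and a *different* atom of the
same water is strictly within 2.5 Å of a flagged atom of `q`.
`bridge_network()` counts, per residue pair, the fraction of frames in
which *any* water bridges the pair; pairs strictly above 40% occupancy
become edges, edges strictly above 60% are *thick*, and each connected
component's hub is its maximal-degree residue (ties to the lower
residue number). The planted-bridge generator places waters in exact
bridging geometry in a seeded choice of `round(f·n_frames)` frames, so
occupancies are recovered exactly.

## 7. Synthetic fixtures and problem sizes

All ground-truth inputs are generated in-package, seeded, and written
as plain text (PDB / restraint files) when persistence is needed. The
sizes are package choices made for exactness and speed: the
path-enumeration oracle caps at 10 nodes (combinatorial), the
largest-empty-circle solver at 300 points per slab (exact enumeration),
and the toy structures at tens of residues. The generators are
geometric test beds — plausible at the Ångström scale, not
stereochemically or thermodynamically realistic — which is sufficient
for the recovery claims they support and is the honest limit of
desk-scale validation for this method family.
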