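---
title: "The freezing string method: model, coordinates, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The freezing string method: model, coordinates, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmpath)
```

## The problem and the method

A chemical reaction corresponds to a pathway on the Born–Oppenheimer
potential energy surface connecting two minima through at least one
first-order saddle point, the transition state (TS). Local saddle
refinement algorithms converge only from a good starting structure, so
the practical bottleneck is producing a TS *guess* cheaply. The freezing
string method (FSM) is a chain-of-states approach tuned for exactly
that: rather than relaxing a whole band of structures to the minimum
energy path (as the nudged elastic band does), it grows two strings
inward from the reactant and the product, gives each newly placed node
only a brief perpendicular relaxation, freezes it permanently, and, when
the strings meet, reports the highest-energy node as the TS guess. The
resulting pathway is deliberately approximate; the payoff is a small,
predictable number of gradient evaluations.

One growth cycle consists of:

1. **Interpolate** a dense path between the current frontier nodes
   (initially the endpoints themselves), using either redundant internal
   coordinates (RIC) or linear synchronous transit (LST).
2. **Step** inward along that path by a fixed arc length `s` from each
   end, giving one new node per side. `s` is fixed at the start as the
   arc length of the initial interpolated path divided by `n_nodes`.
3. **Tangents** at the new nodes come from natural cubic splines of all
   3N coordinates against cumulative arc length of the interpolated
   pathway (which begins and ends at the previously frozen nodes).
4. **Optimize** each new node for at most `n_opt` quasi-Newton steps
   with the gradient replaced by its component perpendicular to the
   tangent, `g⊥ = (I − t̂ t̂ᵀ) g`, then freeze it.
5. **Join** when the frontier gap falls below `join_threshold × s`.

Endpoints are evaluated once at startup and are candidates for the TS
guess, so a barrierless profile cannot spuriously report an interior
maximum.

## Coordinate systems

### Primitive internals and pruning

Bonds are detected with a covalent-radius criterion,
`r < 1.3 (r_cov(a) + r_cov(b))`, from a bundled Cordero-style radius
table; disconnected fragments are joined by their shortest
inter-fragment atom pair, added both as an auxiliary distance coordinate
and as a graph edge (so angles and torsions span the connection and the
fragments' relative orientation is representable). Angles are generated
for every bonded A–B–C, torsions for every bonded A–B–C–D, and one
out-of-plane coordinate at each trivalent center. The reactant and
product sets are unioned (keyed by kind and canonicalized atom tuple)
and pruned, in order:

* angles nearly linear (> 175°) in either endpoint are replaced by two
  *linear bends* along fixed orthogonal axes;
* a linear-bend pair is dropped if the angle deviates from linearity by
  more than 45° (i.e. falls below 135°) in either endpoint — we read the
  45° rule as a deviation-from-linearity bound, since a literal "angle
  > 45°" test would prune essentially every linear bend;
* torsions with |dihedral| > 175° in either endpoint are replaced by an
  A–D distance; torsions with a near-linear internal bend are removed;
* out-of-plane coordinates are removed when a flanking angle at the
  center is near-linear (the coordinate degenerates) or when the
  center's bond set differs between the endpoints (a broken bonding
  center);
* if more than three atoms remain without any torsion, atom quadruples
  are scanned deterministically for one valid in both endpoints;
  failing that, the whole set becomes all unique atom–atom distances.

Pruning is deterministic: identical inputs give an identical ordered
primitive list.

The linear-bend coordinate is implemented as the projection
`u · (â + ĉ)` of the sum of the two unit bond vectors onto a stored
axis perpendicular to the A–C direction (two axes per replaced angle).
This is smooth, has an exact analytic derivative, and equals the bend
angle in radians to first order. The out-of-plane coordinate is the
Wilson-style pyramidalization angle `asin((ê₂ × ê₃) · ê₁)` at the
center. Both definitions are this package's own concrete choices where
the standard assignment procedure leaves the functional form open.

### Delocalization and back-transformation

The Wilson B-matrix holds the exact analytic gradient of each primitive
with respect to the Cartesians (`Δq = B Δx`). Diagonalizing `G = B Bᵀ`
splits primitive space into a nonredundant subspace `U` (eigenvalues
above `10⁻¹⁰ ×` the largest — small enough to keep genuinely soft
combinations, large enough to reject numerical null vectors) and a
redundant remainder. Interpolated targets are converted to Cartesians by
iterating `x_{k+1} = x_k + (Bᵀ)⁻¹ [q_target − q(x_k)]` with
`(Bᵀ)⁻¹ = (B Bᵀ)⁻¹ B` recomputed at every iterate, torsion differences
wrapped onto the shortest signed arc *before* projection by `Uᵀ` (which
is why the conversion API takes primitive-space targets), steps capped
at 0.5 Å per coordinate, and convergence declared when the largest
Cartesian change drops below 10⁻⁷ Å. Non-convergence within 100
iterations returns the smallest-residual iterate flagged approximate.

A subtlety worth knowing: when pruning produces a *redundant* set (e.g.
an exactly anti torsion triggers the trans-planar rule, adding an A–D
distance on top of a full coordinate set), linear targets in the
primitives are not exactly realizable — the back-transform then
converges to the consistent projection in the delocalized subspace. The
internal-coordinate linearity property therefore holds exactly only for
nonredundant systems, and the test suite checks it on one. Likewise the
back-transformed Cartesians are unique only up to rigid motion; which
frame you get is set by the seeding geometry, so forward and reverse
interpolations agree in internals and after superposition, not
coordinate-by-coordinate.

### LST

Each LST node minimizes
`S = Σ_{a>b} (r_ab(f) − r_ab)² / r_ab(f)⁴ + w Σ_j (x_j(f) − x_j)²`
over Cartesians, started from the Cartesian interpolant, with
`w = 10⁻⁶`. The quartic denominator emphasizes short (bonded) distances;
it is floored at `(0.5 Å)⁴` to guard near-coincident interpolated
distances. Nodes are independent in the objective and are optimized
independently (L-BFGS-B, 500-iteration cap, projected-gradient tolerance
10⁻⁸, never accepting a point worse than the start). For a single-atom
system the distance sum is empty and LST degenerates gracefully to
Cartesian linear interpolation — which is precisely what the 2-D
benchmark surface needs.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_nodes` | 18 | – | sets `s` = initial arc length / `n_nodes`; the final string has ≈ `n_nodes` nodes |
| `n_opt` | 2 | – | optimization steps per node; 0 = pure interpolation (energies only for guess selection) |
| `n_ls` | 3 | – | max energy/gradient calls per backtracking line search |
| `max_disp` | 0.3 | Å | per-coordinate bound per optimization step, relative to the step's start |
| `grad_tol` | 10⁻⁴ | energy/Å | early-exit threshold on max-norm of `g⊥` |
| `join_threshold` | 1.5 | × `s` | frontier gap at which the strings are considered met |
| `dense_fractions` | 21 | – | nodes per dense interpolated segment (placement error ≪ `s`) |
| `bond_scale` | 1.3 | – | covalent-radius multiplier for bond detection |
| `lst_w` | 10⁻⁶ | – | LST Cartesian regularization weight |

The defaults `n_nodes = 18`, `n_opt = 2`, `n_ls = 3` are a conservative
baseline; the ablation behavior (below) is the reason the method is
interesting at smaller `n_nodes`. The evaluation budget is strict: a
node costs at most `1 + n_opt × n_ls ≤ n_opt × (1 + n_ls)` calls, and
the per-run ledger reconciles exactly with the calculator's own counter.

## Node optimization

Optimization is performed in Cartesian coordinates. The bounded
limited-memory quasi-Newton scheme is implemented in the package rather
than delegated to `stats::optim`, because the method's contract is
precisely about accounting: each step's trial points must share one
energy-plus-gradient evaluation, at most `n_ls` of them, with the
per-step displacement cap applied relative to the step's start — none of
which a generic minimizer exposes. The scheme keeps 10 correction pairs
(two-loop recursion), projects the search direction onto the plane
perpendicular to the (fixed) tangent, scales the initial trial so no
coordinate moves more than `max_disp`, and backtracks by halving under
an Armijo condition with `c₁ = 10⁻⁴`; if the budget is exhausted the
best-seen point is accepted when it improves the energy, otherwise the
node stays put. The tangent is held fixed during a node's `n_opt` steps:
re-deriving it would require re-interpolation, and tangents are defined
at placement time.

Curvature information accumulated from projected gradients keeps the
quasi-Newton direction effectively in the perpendicular subspace; the
explicit projection of the direction makes the invariant exact
(displacement along the tangent below 10⁻⁸ in the tests).

## Calculators and the synthetic fixtures

The Müller–Brown surface (standard four-Gaussian literature parameters,
hard-coded) is exposed as a single-atom "molecule" with frozen z; RIC
mode refuses single-atom systems with a clear error. The toy force field
— Morse bonds `D(1 − e^{−a(r−r₀)})²`, harmonic angles
`k/2 (θ−θ₀)²`, cosine torsions `V/2 (1 + cos(nφ−γ))`, soft `r⁻¹²`
repulsion between unbonded pairs — assembles its gradient from the same
analytic primitive derivative rows as the B-matrix, so it is exactly
rigid-motion invariant and exercises the full internal-coordinate stack.
The external adapter exchanges XYZ/gradient text files with any program
honoring a small documented contract (Hartree and Hartree/Å, with an
optional bohr-gradient header and documented conversion).

The fixtures module builds endpoint pairs by Z-matrix-style construction
from declared internal values (idealized lengths: C–C 1.54 Å, O–H
0.96 Å, ...), so every template re-measures to its declared values to
10⁻¹⁰. The standard reaction fixture is the butane-like anti (180°) →
gauche (60°) torsion path on a matched force field whose torsional term
has its barrier at 120°; its step sizes (arc ≈ 1.6 Å, `s` ≈ 0.09 Å at 18
nodes) are representative of a small rearrangement. What these fixtures
do *not* emulate: bond breaking across endpoints, competing reaction
channels, PES noise from SCF convergence, or the dimensionality of real
polyatomics — so passing tests demonstrate the machinery and the
method's bookkeeping, not chemical accuracy on real systems, which is
the domain of the electronic-structure calculators the adapter targets.

All randomness (perturbations, displacement draws) funnels through
seeded generators that restore the caller's RNG state; the growth loop
itself is deterministic, and two runs with identical inputs are
bit-identical.

## Numerical choices and degenerate inputs

* Arc length is the unweighted Euclidean norm over all 3N coordinates —
  consistent with the Cartesian framing of the optimizer and LST; no
  mass weighting.
* Two-node paths use the straight-line secant as the "spline" tangent.
* The Kabsch superposition enforces a proper rotation by sign-flipping
  the smallest singular direction; alignment is applied once, at the
  start of a run (the frontier geometries inherit the endpoint frames),
  and skipped for single-atom systems, where centroid matching would
  collapse the two endpoints onto each other.
* Identical endpoints make the step size undefined and raise an error;
  a step request past the remaining path length signals a typed
  strings-meet condition rather than extrapolating.
* When the remaining gap is between `join_threshold × s` and `2s`, one
  midpoint node is placed (from the left string), optimized, and the
  strings join — avoiding a final pair of nearly coincident nodes.
* The delocalized basis `U` is built once, on the reactant geometry (the
  choice of endpoint is not critical for the step sizes involved; using
  one fixed basis keeps interpolation targets consistent across the
  run).
* Torsion arithmetic is everywhere on the circle (shortest signed arc);
  a torsion with exactly collinear internal atoms raises an error naming
  the primitive.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the complete method at
small, fixed sizes chosen to make every check a few seconds: the
Müller–Brown run uses 12 nominal nodes, the toy-FF torsion runs use 18
and 9, the B-matrix finite-difference comparison covers 20 perturbed
fixture geometries, and back-transformation is probed with 10
delocalized displacements of norm 0.3. These sizes are the package's
own validation choices; the algorithm itself has no size assumptions
beyond memory.

## Known limitations

* The FSM pathway is not a converged minimum-energy path; it feeds a
  downstream local TS refinement (P-RFO or similar), which — like
  Hessians, frequencies, and IRC following — is out of scope here.
* No re-optimization after joining (that would be the growing string
  method).
* Coordinate setup and back-transformation scale as O(N³) with atom
  count; fine at force-field and benchmark scale, a bottleneck only for
  very large systems.
* Hybrid delocalized coordinates, translation–rotation–internal sets,
  and geodesic interpolation are deliberate non-goals.
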