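# fsmpath

Transition-state (TS) guess structures and approximate reaction pathways
from reactant and product geometries, via the **freezing string method
(FSM)** with either **redundant-internal-coordinate (RIC)** or **linear
synchronous transit (LST)** interpolation.

Finding a first-order saddle point on a potential energy surface (PES) is
the expensive, failure-prone step of computing a reaction mechanism. The
FSM grows two strings of molecular geometries inward from the reactant
and the product: each growth cycle interpolates a path between the
current frontier nodes, places a new node at a fixed arc-length step *s*
from each end, relaxes it a small, fixed number of steps in the direction
perpendicular to the pathway tangent, and then *freezes* it. When the
strings meet, the highest-energy node is the TS guess, ready for a local
saddle refinement in an electronic-structure code. Because each node is
optimized only briefly and never revisited, the cost in gradient
evaluations stays low — at the price that the final string only
approximates the true minimum-energy path.

The two interpolators are the scientific core:

* **RIC** — primitive internal coordinates (bonds, angles, linear bends,
  torsions, out-of-plane angles) are detected on both endpoints, pruned
  with near-linearity heuristics, and unioned; targets are interpolated
  linearly, `q(f) = (1−f) q_R + f q_P` (torsions along the shortest
  arc), and converted back to Cartesians by iterating the Wilson
  B-matrix relation `x_{k+1} = x_k + (B^T)⁻¹ [q_target − q(x_k)]` in the
  delocalized (nonredundant) basis `U` from diagonalizing `G = B Bᵀ`,
  to a 10⁻⁷ Å step tolerance.
* **LST** — each node minimizes
  `S = Σ_{a>b} (r_ab(f) − r_ab)² / r_ab(f)⁴ + w Σ_j (x_j(f) − x_j)²`,
  a least-squares fit to linearly interpolated internuclear distances
  with a small Cartesian regularizer (`w = 10⁻⁶`).

Node optimization minimizes the energy with the gradient replaced by the
perpendicular component `g⊥ = (I − t̂ t̂ᵀ) g`, using a bounded L-BFGS
scheme (10 correction pairs, ≤ 0.3 Å per coordinate per step) with a
backtracking Armijo line search of at most `n_ls` energy/gradient calls.

Energies and gradients come from pluggable calculators, so the full
algorithm runs and is tested without quantum chemistry: the analytic
Müller–Brown surface, a toy molecular force field (Morse bonds, harmonic
angles, cosine torsions), or a file-based adapter around any external
program that can write an energy and gradient to a text file.

## Worked example

A butane-like anti → gauche torsional rearrangement on the matched toy
force field, with FSM-RIC:

```r
library(fsmpath)

pair <- make_pair(fixture_spec("butane-like", torsion = 180),
                  fixture_spec("butane-like", torsion = 60))
calc <- toyff_calculator(butane_toyff())
state <- run_fsm(pair$reactant, pair$product, calc,
                 fsm_config(n_nodes = 18, n_opt = 2, n_ls = 3,
                            interpolator = "ric"))
state
#> <fsm_string: 20 nodes, TS guess at node 12, E_max = 8.84846, 75 gradient calls>

measure_primitives(state$ts_guess, primitive("torsion", 1:4)) * 180 / pi
#> [1] 116.9677
```

The string joined after 20 frozen nodes and 75 gradient evaluations; the
TS-guess torsion of 117.0° sits 3.0° from the 120° maximum of the
force field's torsional term — the barrier the path must cross. Halving
`n_nodes` to 9 reproduces the same guess (117.0°) in 35 gradient calls,
a 53% cost reduction from taking larger interpolation steps.

On the two-dimensional Müller–Brown surface (a single-particle system,
where LST reduces to Cartesian interpolation):

```r
st <- run_fsm(mb_minimum("A"), mb_minimum("B"), mb_calculator(),
              fsm_config(n_nodes = 12, n_opt = 2, n_ls = 3,
                         interpolator = "lst"))
st$ts_guess$coords[1, 1:2]
#> [1] -0.8030625  0.6066318
```

The highest-energy node lands 0.026 units from the upper saddle point at
(−0.822, 0.624) located by an independent Newton search, using 55
gradient evaluations.

Shell entry points live in `inst/scripts/`:

```sh
Rscript inst/scripts/fsm_fixtures.R --template butane-like --out pair/
Rscript inst/scripts/fsm_run.R --reactant pair/reactant.xyz \
  --product pair/product.xyz --calc toyff:pair/toyff.yaml \
  --interp ric --n-nodes 18 --out out/
```

`out/` then contains `string.xyz` (the full pathway, energies in the
comment lines), `profile.tsv`, `ts_guess.xyz`, `run.log`, and
`config.yaml`.

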