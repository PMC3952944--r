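---
title: "Tree-based sampling of conformational transition paths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based sampling of conformational transition paths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtree)
```

## The problem

Many proteins carry out their function by switching between structurally
distinct states.  Trajectory methods (molecular dynamics) resolve such
transitions in time but at a cost that grows prohibitive for rare events.
`pathtree` takes the complementary, robotics-inspired view: it searches
*conformational space* directly for a **series of physically-realistic
conformations** connecting a given start structure to a goal region around a
given goal structure.  The result is a set of conformational paths — ordered
milestones a transition could pass through — not time-resolved trajectories.

The search grows a tree rooted at the start conformation.  Each iteration
selects a node for expansion (biased by one or two discretization layers)
and tries to extend it with a *molecular fragment replacement* move screened
by the Metropolis criterion.  Nodes that come within a tolerance `tol`
(lRMSD) of the goal terminate paths.

## Chain model

A conformation of an `n`-residue chain is its backbone dihedral vector: phi
and psi per residue, 2n angles, under the **idealized geometry** assumption
— bond lengths and angles fixed at canonical values (CHARMM22/Engh-Huber
class defaults in `geometry_params()`, every value overridable), omega fixed
at 180 degrees (trans; no cis-proline handling).  Only the four backbone
heavy atoms N, CA, C, O are modeled.  `forward_kinematics()` realizes
cartesian coordinates from angles; `measure_dihedrals()` inverts it.

Conventions that make trees bit-for-bit reproducible:

* **Anchor**: N1 at the origin, CA1 on the +x axis, C1 in the xy-plane with
  positive y.  Coordinates are therefore a pure function of the angle
  vector, and a fragment move at window *i* leaves all atoms of residues
  < *i* bitwise unchanged.
* **Torsion sign**: the standard structural-biology convention (verified
  against independent implementations in the test suite); degrees on
  [-180, 180) externally, radians internally.
* **Sentinels**: phi of residue 1 and psi of residue n are undefined in a
  linear chain and stored as `ANGLE_UNDEF` (999.0).  The carbonyl O of the
  last residue, whose ideal placement references the (nonexistent) next N,
  is placed at an N-CA-C-O torsion of 180 degrees.

## Fragment replacement

Moves overwrite the 6 dihedrals of a trimer window (k = 3) with a
configuration excised from known structures.  Short fragments deliberately
bound the conformational jump per move.  `build_library()` supports two
modes: **position-independent** (default; every source trimer available at
every window — appropriate when sources are unrelated structures) and
**position-specific** (source position i feeds window i only — appropriate
when sources share the target's length, e.g. the endpoint structures
themselves).  Libraries round-trip through a plain-text format with
`#mode` / `#n` headers so they can be inspected and diffed.  Sentinel slots
in terminal windows are skipped when copying, so termini never acquire
fake angles.

## Energy

Energy enters only through the Metropolis screen, so the planner is
deliberately agnostic to the potential: any object implementing
`evaluate_energy()` works.  Three tiers ship with the package:

* `energy_amw()` — a coarse-grained five-term potential in the
  Lennard-Jones + H-bond + contact + burial + water family: soft-core 12-6
  LJ over backbone atoms (constant cap below a penetration fraction of
  sigma, cubic switching between 7 and 8 Angstrom), a distance-and-angle
  N...O backbone H-bond well, and smoothed sigmoid contact/burial/water
  terms over CA distances.  Parameters are simplified, documented defaults,
  all pluggable; no claim in this package rests on reproducing any
  published force-field numerics.
* `energy_goal_funnel()` / `energy_barrier()` — analytic toy landscapes
  (`scale * lRMSD`-to-goal, optionally plus a Gaussian bump of chosen
  height and width centred at delta-R = 0) whose every property is known,
  used by the planner test-suite so planner correctness is never
  conditioned on force-field fidelity.
* `energy_zero()` / `energy_reject_all()` — degenerate models for
  exercising the acceptance and exhaustion paths.

Units are kcal/mol throughout, with kB = 0.0019872 kcal/(mol K).  Energies
are recomputed on demand rather than cached on conformations: at this
coarse-grained scale a forward-kinematics pass is cheaper than reliable
cache invalidation across fragment moves, and the planner already reuses
the coordinates it computes per candidate.

## Metrics and discretization layers

**lRMSD** (`lrmsd()`) uses the closed-form Kabsch superposition restricted
to proper rotations (the reflection branch is rejected by sign-flipping the
smallest singular value), uniform weights over the 4n modeled atoms, atoms
paired by index.  The test suite checks it against a brute-force
Euler-angle rotation search to 1e-3 Angstrom.

**Progress grid**: nodes are binned by lRMSD-to-goal into integer levels of
1 Angstrom spacing on [0, D], D = ceiling of the start-goal lRMSD; values
beyond D map to level D, values on a boundary go up (floor convention).
Level weights:

* `QUAD` — w(l) = 1/(1 + l^2) + epsilon
* `LINEAR` — w(l) = 1/(1 + l) + epsilon
* `UNIFORM` — w(l) = 1/#levels
* `COMBINE` — each draw uses UNIFORM with probability 0.9, else QUAD

Selection probabilities renormalize over *occupied* levels only, so a draw
never lands on an empty level (the alternative — redrawing — would waste
RNG and bias nothing).  `epsilon` defaults to 1e-6: large enough to keep
distant levels reachable, small enough not to perturb the intended bias.

**Shape grid** (optional): conformations project to three
ultrafast-shape-recognition features — mean atom distance from the
centroid, from the atom farthest from the centroid, and from the atom
farthest from that atom (ties broken to the lowest atom index for
determinism).  Cells of 0.25 Angstrom per feature (configurable; finer
granularity sharpens the diversity pressure at the cost of emptier cells)
are weighted 1/((1 + nsel) * nconfs), penalizing cells selected often or
already crowded.  `nsel` increments on every selection, including those
whose subsequent expansion fails: fruitless regions should lose weight too.
The shape layer applies identically under all level schemes.

**delta-R** (`delta_r()`): lRMSD to one reference minus lRMSD to another; a
1-D transition coordinate used for pseudo-free-energy profiles.

## Expansion, local bias, step control

From a selected parent, up to `l` fragment moves are proposed (default
100); each proposal is accepted into the candidate set with the Metropolis
probability exp(-dE/kB T); proposing stops once `m` candidates pass
(default 10).  The candidate with the lowest lRMSD-to-goal is taken —
unless **step control** is on, in which case the mean and standard
deviation of candidate-to-parent lRMSDs define a Gaussian, one value is
drawn, and the candidate nearest the draw is taken (single candidate or
zero spread degenerate to the mean; ties to the lowest index).  Under
**local bias** the chosen candidate is added only if it does not increase
lRMSD-to-goal over the parent.  A failed expansion is a normal outcome: it
consumes an iteration but adds no node.  `max_nodes` counts added nodes; a
hard cap of `max_iter_factor * max_nodes` total iterations (default 50x)
guarantees termination when expansions keep failing.

A single RNG stream drives every stochastic choice in a fixed order
(COMBINE scheme draw, level draw, cell draw, node draw, then per-attempt
window/config draws and Metropolis uniforms, then the step-control
Gaussian), so a seed reproduces the tree exactly.

## Temperature

The 15-temperature schedule is geometric ("proportional cooling"):
T_k = T0 (T14/T0)^(k/14), with T14 = 300 K and T0 defined by a Metropolis
acceptance of 0.5 for a 10 kcal/mol increase — T0 = 10/(kB ln 2), about
7260 K.  Note an ambiguity two reasonable conventions create for the fixed
"medium" temperature: schedule index 9 gives ~936 K, while calibrating
"accepts 10 kcal/mol with probability 0.1" gives ~2186 K
(`medium_temperature()`).  The planner defaults to schedule T9 and exposes
both.

The **reactive controller** watches non-overlapping windows of `w` added
nodes (default 100).  Let `improvement` be the previous window's best
(lowest) lRMSD-to-goal minus the current window's best.  Improvement below
d1 (default 0.25 Angstrom) *raises* the temperature — index moves down,
toward T0; improvement of at least d2 (default 1.5) lowers it — index up,
toward T14; the index clamps to [0, 14].  Raising on stalls buys
barrier-crossing ability; lowering on fast progress restores path
resolution.  The window statistic is the best among nodes *added during the
window* (not the global tree best), and a tie with the previous window
counts as no improvement.

## Analytics

* **Depth**: minimum lRMSD-to-goal over the tree.
* **Paths**: one per goal-region node, traced through parent links.
* **Breadth**: paths are aligned by distance-from-goal index i = 0..h-1,
  h = length of the shortest successful path; longer paths contribute their
  h nodes nearest the goal.  With d_i the maximum pairwise lRMSD among
  conformations at index i, b = sum (i+1) d_i / h.  Each of the h indices
  contributes exactly once; the (i+1) factor down-weights disagreement near
  the goal, where paths necessarily converge.
* **Reference proximity**: per reference structure, the minimum lRMSD over
  all conformations on qualifying paths.
* **Pseudo-free energy**: a single-ensemble Boltzmann histogram,
  F = -kB T ln(count/total) per bin, shifted to minimum 0, empty bins +Inf.
  This deliberately replaces multi-window reweighted estimators: profiles
  here are descriptive summaries of sampled paths, not equilibrium free
  energies, and carry no statistical reweighting across sampling
  conditions.

## The synthetic generator

`make_toy_transition()` builds fully self-contained instances: a random
goal, a start produced by overwriting every trimer window with a decoy
configuration, and a library holding — per window — the goal's own trimer
plus `decoys_per_window` decoys.  Reachability is a construction invariant
(`reachability_certificate()` returns an explicit move list reaching the
goal exactly), so planner tests never rely on luck for a solution to exist.

Two decoy regimes matter:

* **Random decoys** (default): decoys are uniform over angle space.  Moves
  then make large jumps (1-4 Angstrom in lRMSD for 8-14 residue chains),
  which is the right regime for reachability and bias-scheme experiments.
* **Jittered decoys** (`decoy_jitter`, degrees): decoys are the goal
  configuration plus bounded uniform noise.  Transitions then decompose
  into many small steps, which is the regime where an energy barrier on
  the delta-R axis is meaningful: with large random moves a Gaussian bump
  is simply leapt over in one move, while small steps must climb it under
  Metropolis control.  The barrier experiments use jitter of 25 degrees, a
  60 kcal/mol bump of width 0.5 Angstrom on chains of 14 residues — chosen
  so that per-move energy increments are several multiples of kB T at the
  medium temperature but a modest fraction of kB T0.

Because a tree retains every accepted intermediate, it *ratchets* over
barriers: unlike a Markov chain it never loses partial progress.  Barriers
therefore only bite when per-move uphill increments are individually
improbable at the current temperature, which is what the jittered regime
arranges.

Toy energies drive all planner tests; the five-term model is exercised by
its own unit tests only.  An "extended" conformation, where needed for
demonstrations, is all defined angles at 180 degrees.

## Test problem sizes

The suite verifies structural invariants on a 2,000-node exploration
(10 residues), reachability on ten 1,500-node runs (10 residues, 2
decoys/window), the reactive-vs-fixed comparison on twenty 600-node runs
per arm (14 residues), and the bias-scheme comparison on eight 400-node
runs per scheme (12 residues, 6 decoys/window).  These sizes are the
package's chosen study conditions for chains one-tenth the size of a real
signaling protein; statistical checks (Metropolis rates, selection
frequencies) use 1e4-1e5 draws against closed forms at chi-square /
3-sigma criteria.

## Known limitations

* Toy landscapes have no corridor structure: any window order reaches the
  goal, so path diversity is decoy-driven and nearly identical across
  selection schemes.  The expectation that softer global bias yields
  *higher* breadth — which on real, rugged protein landscapes comes from
  greedy bias funnelling paths through a single corridor — does not
  separate beyond noise on these toys, and the corresponding acceptance
  expectation documents this honestly rather than asserting a weakened
  form.  Depth-related patterns (stronger bias reaches a given depth in
  fewer added nodes; reactive temperature rescues barrier-blocked runs) do
  reproduce on toys.
* No side chains, no bond-length/angle flexibility, no cis peptide bonds;
  paths are milestone sequences, not trajectories, and pseudo-free-energy
  profiles are descriptive only.
* The five-term energy is structurally faithful to its family but
  numerically uncalibrated; quantitative energetics require supplying a
  parameterized model through the `energy_model` contract.
* Start/goal residue correspondence is positional over shared residue
  numbers; sequence alignment for non-identical sequences is out of scope.
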