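# pathtree

Sampling conformational transition paths in proteins with a tree-based,
robotics-inspired planner.

Proteins that switch between functional states traverse conformational
space along paths that are hard to observe experimentally and expensive to
simulate dynamically. `pathtree` searches for such paths directly: it grows
a tree of backbone conformations rooted at a **start** structure and steers
it toward a **goal region** — all conformations within a tolerance lRMSD of
a **goal** structure. Structural deformations are proposed by *molecular
fragment replacement* (overwriting the six phi/psi dihedrals of a trimer
window with a configuration excised from known structures) and screened by
the Metropolis criterion, so consecutive conformations along a path stay
physically realistic and energetically credible. The package is aimed at
method developers and structural bioinformaticians studying transitions in
small-to-medium proteins (tens to a few hundred residues).

## The method in brief

* **Representation.** Idealized geometry: bond lengths/angles fixed, omega
  trans; a conformation is the 2n vector of phi/psi dihedrals over the N,
  CA, C, O backbone atoms. Forward kinematics realizes coordinates.
* **Selection (global bias).** Tree nodes are binned by their
  lRMSD-to-goal into 1 Å levels on [0, D]. A level is drawn with
  probability proportional to w(l) — `QUAD` w(l) = 1/(1+l²)+ε, `LINEAR`
  1/(1+l)+ε, `UNIFORM` 1/#levels, or `COMBINE` (90% UNIFORM / 10% QUAD) —
  then optionally a cell of a 3-D shape grid (ultrafast-shape-recognition
  projection) with weight 1/((1+nsel)·nconfs), then a node uniformly.
* **Expansion (local bias).** Up to `l` fragment moves are proposed until
  `m` pass Metropolis at temperature T; the lowest-lRMSD-to-goal candidate
  is added (optionally only if it improves on the parent; optionally chosen
  instead by a Gaussian step-size rule).
* **Temperature.** A 15-step geometric schedule from T0 ≈ 7261 K (accepts
  10 kcal/mol with probability 0.5) down to T14 = 300 K. A reactive
  controller raises the temperature when windowed progress stalls
  (improvement < d1 = 0.25 Å per w iterations) and lowers it when progress
  is fast (≥ d2 = 1.5 Å).
* **Analytics.** Tree depth (best lRMSD-to-goal), per-path extraction,
  breadth b = Σ (i+1)·d_i / h over successful paths, proximity of paths to
  reference structures, and pseudo-free-energy profiles along the
  ΔR = lRMSD(·,A) − lRMSD(·,B) coordinate.

## Worked example

```r
library(pathtree)

# a self-contained toy transition: 10 residues, 2 decoy fragment
# configurations per window, goal reachable by construction
toy <- make_toy_transition(10, decoys_per_window = 2, seed = 42)

cfg <- planner_config(tol = 0.5, max_nodes = 500, scheme = "COMBINE",
                      seed = 1)
res <- run_planner(toy$start, toy$goal, toy$lib, toy$model, cfg)
res
#> planner_result: 501 nodes (root included), 189 goal-region nodes, depth = 0.000 A

tree_depth(res)            # best lRMSD-to-goal over the tree (Angstrom)
#> [1] 4.180373e-15

paths <- extract_paths(res)
length(paths)              # one path per goal-region node
#> [1] 189
path_breadth(res, paths[1:20])
#> breadth b = 10.962 A over shortest-path length h = 7
```

A depth of ~1e-15 means the tree reached the goal exactly (the goal's own
fragment configurations are in the toy library); each extracted path is a
root-to-goal chain of conformations, and the breadth statistic summarizes
how structurally diverse the successful paths are (0 would mean all paths
identical; here the first 20 paths disagree by several Angstrom at each
of the h = 7 aligned levels, weighted toward the root end).

Real structures enter through `read_pdb_backbone()` (one chain, N/CA/C/O,
first altlocs, incomplete residues dropped), `align_records()` for
positional residue correspondence, and `build_library()` for fragment
libraries from PDB sources. A thin command-line driver is included:

```sh
Rscript inst/scripts/pathtree-cli.R --start start.pdb --goal goal.pdb \
    --library frags.txt --config run.cfg --out outdir --seed 1 --repeats 3
```

writing per-run tree logs, temperature traces, best-path multi-model PDBs,
and a depth summary (mean ± sd over repeats).

## Package layout

| Area | Functions |
| --- | --- |
| Chain model | `conformation`, `geometry_params`, `forward_kinematics`, `measure_dihedrals` |
| Fragments | `build_library`, `sample_move`, `apply_move`, `read/write_fragment_library` |
| Energy | `energy_amw`, `energy_goal_funnel`, `energy_barrier`, `energy_zero`, `evaluate_energy` |
| Metrics | `lrmsd`, `usr_features`, `progress_level`, `delta_r` |
| Temperature | `temperature_schedule`, `acceptance_probability`, `metropolis_accept`, `reactive_config`, `reactive_update` |
| Planner | `planner_config`, `run_planner`, `select_parent`, `expand_node`, `step_size_select`, `level_weight` |
| Analysis | `extract_paths`, `tree_depth`, `path_breadth`, `reference_proximity`, `pseudo_free_energy`, `path_delta_r` |
| I/O + CLI | `read_pdb_backbone`, `write_path_pdb`, `read/write_run_config`, `cli_run` |
| Fixtures | `make_toy_transition`, `reachability_certificate` |

The methods vignette (`vignettes/conformational-path-sampling.Rmd`) details
the model, conventions, parameter choices, and known limitations.
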