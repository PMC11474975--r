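# pocketdyn

Trajectory analysis of protein binding-pocket dynamics in R.

Enzymes such as acetylcholinesterase (AChE) bury their catalytic machinery
at the bottom of a deep, narrow active-site gorge. Understanding how
inhibitors bind — and why the same inhibitor behaves differently in, say,
the mosquito enzyme (AgAChE1) and the mouse enzyme (mAChE) — requires
analysing long molecular-dynamics (MD) trajectories of the apo enzymes and
of enzyme–inhibitor complexes: which binding poses the ligand visits, how
the gorge breathes, where the water sites are, and which residues pay for
the binding. `pocketdyn` implements that analysis stack as a tested R
package, together with deterministic synthetic systems that stand in for
MD data in the test suite.

## What it computes

**Binding-pose clustering from reciprocal minimum distances** (the core
method). For each trajectory frame, the minimum distance d(i,j) between
every protein residue *i* (heavy atoms) and every ligand fragment *j* is
computed and featurized as

    f(i,j) = 1 / max(d(i,j), 0.5 Å)

Reciprocation suppresses the fluctuations of distant residues and
amplifies contacts, so the feature variance is dominated by changes in the
interaction pattern. The frames × (residues × fragments) feature matrix is
reduced by PCA to 3 components and clustered with K-means; the cluster
count is chosen by maximising the Silhouette score among candidates whose
Davies–Bouldin index ranks lowest or second lowest. No superposition and
no frames × frames RMSD matrix are ever needed, so memory stays
O(frames × features).

**Essential-dynamics PCA.** Eigendecomposition of the mass-weighted
covariance matrix of superposed main-chain coordinates; projections,
PC-overlap between ensembles (e.g. apo vs complex), interpolated
extreme-motion trajectories, and conformational-state clustering with the
elbow rule (2.5 % threshold on the SSR/SST curve).

**Gorge-radius profiling.** HOLE-style largest-inscribed-sphere radii in
0.5 Å slices along the gorge axis, found by an annealed Monte-Carlo search
(2000 steps per slice, marching outward from a seed atom), plus axial
position distributions of the gorge-lining residues.

**Water-site occupancy.** Average number of water molecules whose oxygen
lies strictly within 3.0 / 3.5 Å of selected site atoms, with apo-vs-complex
percent-change comparison.

**Per-residue MM interaction energies.** Vacuum Coulomb
(f·Σ qᵢqⱼ/rᵢⱼ, f = 138.935458 kJ·mol⁻¹·nm·e⁻²) and Lennard-Jones
(Lorentz–Berthelot) terms between the ligand and every residue, averaged
over cluster-representative frames (20 frames nearest the cluster centre,
pairwise ≥ 20 frames apart), filtered at ≤ −4 kJ/mol for noncharged
residues. Poisson–Boltzmann and surface-area solvation are out of scope;
reported numbers are MM terms only.

**I/O.** PDB (fixed-column), GRO and CHARMM/NAMD DCD reading and writing,
an atom-selection mini-language, replicate trimming/concatenation, and a
global-alignment sequence identity/similarity utility (Needleman–Wunsch,
BLOSUM62, gap 10/0.5).

## Worked example

```r
library(pocketdyn)

## a synthetic 3-pose protein-ligand trajectory (ground truth known)
ps <- make_pose_trajectory(n_frames = 3000, seed = 7)

dm  <- min_distance_matrix(ps$traj, fragments = ps$fragments)
fe  <- reciprocal_features(dm)           # 3000 x 60, 1/Angstrom
fp  <- feature_pca(fe, n_components = 3)
res <- cluster_poses(fp$projection, 2:10, seed = 7)
res
#> pose_clusters: k = 3, populations 33.3%/33.3%/33.3%

adjusted_rand_index(res$labels, ps$labels)
#> [1] 1
```

The model selection table behind that choice (`res$metrics`) shows k = 3
with the highest Silhouette score (0.95) and the lowest Davies–Bouldin
index (0.07): the three planted binding poses are recovered exactly, with
populations matching the planted occupancies. Downstream,
`decompose_clusters()` + `filter_contributors()` list the residues that
interact favourably with the ligand in each pose, e.g.

```r
#>  cluster residue_name residue_number coulomb    lj  total
#>        1          ALA             15  -11.86 -1.34 -13.20
```

## CLI

A thin wrapper script is installed at `inst/scripts/pocketdyn`:

```sh
pocketdyn simulate poses --frames 3000 --seed 7 --out sim/
pocketdyn cluster-poses --top sim/topology.pdb --traj sim/traj.dcd \
    --k 2:10 --seed 7 --out clusters/
pocketdyn energy --top sim/topology.pdb --traj sim/traj.dcd \
    --params sim/ff_params.tsv --labels clusters/pose_labels.tsv \
    --projections clusters/feature_projection.tsv --out energy/
```

Every run writes a `run_record.json` (command, parameters, input digests,
seeds, version) next to its outputs.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main pipeline from scratch —
generating the synthetic pose system at the given seed, featurizing,
clustering, and decomposing the interaction energies — and writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
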