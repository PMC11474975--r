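---
title: "Methods: binding-pocket trajectory analysis with pocketdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-pocket trajectory analysis with pocketdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketdyn)
```

`pocketdyn` analyses molecular-dynamics trajectories of enzymes whose
active site sits at the bottom of a deep channel (the "gorge" of
acetylcholinesterases is the motivating case). This vignette documents the
models and procedures, the parameters that matter, the synthetic systems
used as the test bed, and the numerical and design choices behind the
implementation. Units throughout: Ångström, nanoseconds, amu, kJ/mol,
elementary charges; trajectory formats that store nm (GRO) are converted
at the I/O boundary.

## 1. Pose clustering from reciprocal minimum distances

The central method represents each protein–ligand conformer by its
interaction pattern instead of its Cartesian coordinates. For frame $t$,
residue $i$ and ligand fragment $j$:

$$ f_{ij}(t) = \frac{1}{\max\{d_{ij}(t),\, d_0\}}, \qquad
   d_{ij}(t) = \min_{a \in i,\, b \in j} \lVert x_a(t) - x_b(t) \rVert $$

with $d_0 = 0.5$ Å. Distances are internal coordinates, so the
featurization needs no superposition and is exactly invariant under rigid
motions of each frame; reciprocation compresses the variance of residues
far from the ligand ($f \to 0$) and expands contact-range variation. The
floor $d_0$ bounds features at atomic contact; MD conformers never reach
it, but robustness demands it.

The frames × P feature matrix (P = residues × fragments) is column-mean
centred and reduced to its first three principal components (plain
covariance PCA, no mass weighting — the features are not coordinates).
K-means (k-means++ initialisation, 10 restarts, Lloyd iterations, fixed
seed) is run for each candidate k, and k is chosen by **maximising the
Silhouette score subject to the Davies–Bouldin index ranking lowest or
second lowest** among the candidates; ties go to the smaller k. The
published procedure combines these indices with visual inspection, which
cannot be automated; the deterministic rule above is the package's
codification and is pinned by tests. If no candidate satisfies the DB
constraint (possible only when every DB value is undefined), the full
metric table is returned with status `"no_admissible_k"` rather than a
silent choice. Above 5000 frames the Silhouette is computed on a
fixed-seed subsample of 5000 (it is O(n²)); the DB index always uses all
frames.

Per cluster, the *central structure* is the frame nearest the centroid in
the 3-PC feature space, and the representatives are the up-to-1000 nearest
members in ascending distance. Everything downstream (energy decomposition)
consumes these.

Memory stays O(frames × P): no frames × frames matrix is ever formed,
which is what makes the method usable on multi-microsecond trajectories
where RMSD-matrix clustering is prohibitive.

**Ligand fragmentation.** When no fragment definition is supplied, bonds
are perceived by distance (heavy–heavy < 1.85 Å, 2.1 Å to S/Cl/Br), rings
are detected on the bond graph, and fragments are the connected components
left after cutting every acyclic bond between two non-terminal atoms where
at least one side carries a ring or ≥ 3 atoms. This is a pragmatic
stand-in: real reproductions should supply the chemically meaningful
fragment list via `fragment_scheme()`.

## 2. Essential-dynamics PCA and conformational clustering

Frames are least-squares superposed (Kabsch, proper rotation enforced)
onto a reference on the analysis selection (typically `main_chain`),
coordinates are weighted by $\sqrt{m_i}$ when `mass_weighted = TRUE`, and
the 3M × 3M covariance of the flattened coordinates is eigendecomposed.
For 3M > 5000 the frame-space Gram matrix is decomposed instead; the
non-zero spectra of the two routes agree to numerical precision. Mean
projection is zero by construction, PC scores decorrelate, and the
eigenvalue sum equals the covariance trace (tested at 10⁻⁸ relative).

Conventions worth stating:

* **Covariance denominator** is the frame count (population covariance),
  matching trajectory-analysis practice.
* **Eigenvector sign**: each column is oriented so its largest-magnitude
  component is positive, making runs reproducible; `flip_pc_sign()` exists
  purely for presentation parity when comparing species.
* **PC overlap** between two models on the same selection is the inner
  product of unit eigenvectors, sign retained. It measures conservation of
  a collective motion between ensembles (apo vs complex).
* **External structures** are superposed to the PCA reference on the model
  selection before projection. Energy minimisation of such structures is
  out of scope; projections of un-minimised crystal structures land in the
  same basin but not the identical point.
* **Extreme-motion interpolation** reconstructs $\mu + s\,v_k$ for $n$
  values of $s$ spanning the observed projection range; weights are
  un-applied so the output trajectory is Cartesian.

Conformational states are found by K-means on the first three PCs with the
**elbow rule**: SSR/SST(k) is the within-cluster over total sum of squares,
and the chosen k is the smallest whose improvement to k+1 drops below the
threshold (default 2.5 %). The source procedure states the threshold but
not the exact rule form; the consecutive-drop form is pinned here. One
consequence, verified empirically: an isotropic structureless Gaussian
does *not* map to k = 1 under any absolute-drop rule (its SSR/SST curve
declines smoothly, with drops above 2.5 % until k ≈ 6); the degenerate
guarantee the package does make is that a zero-variance projection yields
k = 1. On genuinely multi-modal projections (the intended regime) the rule
recovers the planted k exactly. `k_max` defaults to 10, a documented
choice.

## 3. Superposition, RMSD, RMSF

Fits are unweighted by default (mass-weighted on request), reflecting the
defaults of the standard trajectory tools; the reference defaults to the
first frame, standing in for the equilibrated starting structure. No
periodic-boundary unwrapping is attempted — inputs are assumed whole.
RMSF is computed in two passes (mean, then squared deviations) to avoid
catastrophic cancellation at Å-scale coordinates.

A subtlety the tests account for: fitting removes 6 rigid-body degrees of
freedom, so the isotropic closed form RMSF $= \sqrt{3}\sigma$ is observed
shrunk by $\approx\sqrt{1 - 6/(3N)}$; with N = 100 atoms the ~1 % bias
sits comfortably inside the 2 % verification band.

## 4. Gorge-radius profiling

The channel axis is rotated onto Y (`align_gorge_axis`, Rodrigues
rotation + per-frame Cα Kabsch fit), and for each 0.5 Å slice the largest
sphere radius

$$ r(c) = \min_a \left( \lVert c - x_a \rVert - R^{vdW}_a \right) $$

is maximised over the slice plane by an annealed random walk: 2000
Gaussian proposals, accept on improvement, step size (default 0.1 Å)
halved after 50 consecutive rejections. Slices are processed marching
outward from the seed slice, each initialised at the neighbouring
optimum — this warm start is also what makes the estimate provably
monotone under atom deletion when re-run from a previous profile's
centres. The search is restricted to the slice plane (2 dof), matching
fixed-axis usage rather than full 3-D pore tracing. Van der Waals radii
default to the Bondi set (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å);
HOLE's AMBER-derived defaults differ slightly, so exact numeric parity
with HOLE is not claimed — the analytic fixtures pin correctness instead.
Waters, ions and the ligand are excluded from the blocking set by default.

A residue "lines the gorge surface" at a slice when any heavy atom lies
within (radius + vdW + 1.0 Å margin) of the optimal sphere centre; pooled
over frames this gives the axial position distribution per residue.

## 5. Water-site occupancy

A water's position is its oxygen (the single heavy atom of three-site
water models), and the cutoff comparison is strictly `<`, resolving
boundary cases by the stated convention. Counting uses a bounding-box
prefilter whose final comparison is identical to the naive loop, so counts
are bit-equal to brute force. No periodic-image search is done by default:
gorge sites sit far from box boundaries. Percent change between apo and
complex tables is (other − reference)/reference × 100, with a zero
reference flagged `undefined` rather than raising.

## 6. Per-residue MM interaction energies

For cluster representatives, the ligand–residue interaction is the vacuum
molecular-mechanics pair sum with no cutoff: Coulomb
$f \sum q_i q_j / r_{ij}$ with $f = 138.935458$ kJ mol⁻¹ nm e⁻², and
Lennard-Jones $4\varepsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$
under Lorentz–Berthelot combination. Additivity (per-residue sums equal
the whole-interface double loop) is an exact identity and is tested at
10⁻⁶ relative. Distances below 0.05 nm raise a clash error; missing
parameters are reported by atom, never defaulted.

Frame selection codifies "the 20 frames closest to the central structure,
evenly spaced by 20 frames" as a greedy walk of the distance-ranked member
list that takes a frame only if its trajectory index differs by ≥ 20 from
every frame already taken. For consecutive-frame clusters this admits few
frames (by design — the point is decorrelation); the function warns when
it returns fewer than requested.

The Poisson–Boltzmann and surface-area terms of an MM-PBSA estimate
require an external solver and are deliberately absent; outputs are
labelled MM terms to prevent conflation with full binding energies.
Charged residues (Asp/Glu/Lys/Arg/His⁺ by residue name; nonstandard
protonation must be declared) are reported separately by
`filter_contributors()` because their unscreened Coulomb terms are not
comparable to the noncharged ones; noncharged residues are filtered at
≤ −4 kJ/mol and banded at ≤ −5 ("favorable") and ≤ −10 ("strong").

## 7. The synthetic test bed

No MD data accompanies the methodology, so the package ships generators
whose ground truth the test suite consumes directly. All are
bit-reproducible from (parameters, seed) and leave the caller's RNG state
untouched.

* **`make_pose_trajectory`** — a ring of residues (backbone + two
  inward-pointing side-chain carbons) with a rod ligand of linked 3-atom
  rings. Each frame sits in one planted pose: ligand side-chain distances
  < 4 Å to that pose's 3-residue contact arc and > 8 Å to every other
  residue (verified constructively). The pose sequence is built from
  dwell blocks (default 10 frames) with *exact* per-pose block counts,
  shuffled under the seed, so label histograms match the occupancies up to
  block granularity. Default noise: 0.2 Å Gaussian per coordinate — small
  enough that poses stay separable, large enough that bond perception on a
  noisy frame is non-trivial. What it does **not** emulate: ligand
  flexibility, gradual pose interconversion, or correlated protein
  motions; a green recovery test therefore establishes the pipeline's
  correctness on well-separated interaction patterns, not its resolution
  limit on overlapping ones.
* **`make_channel`** — wall atoms on rings along Y. The rings sit on the
  *envelope* of the inscribed spheres of radius R(y) + vdW (ring height
  $t - FF'$, ring radius $F\sqrt{1-F'^2}$, $F = R + vdW$), so the analytic
  pore radius is exactly R(y) even for sloped walls — placing atoms
  naively at R(y) + vdW makes the perpendicular-limited inscribed radius
  smaller than R(y) for any non-cylindrical profile. Requires |R′| < 1.
  Optional breathing adds a sinusoidal time modulation.
* **`make_waterbox`** — a tyrosine hydroxyl site at the origin with waters
  placed per-frame inside/between/outside the cutoffs, with a 0.2 Å guard
  band on both sides of each cutoff so the expected occupancy table is
  exact and boundary semantics are never left to floating-point luck.
* **`make_harmonic`** — isotropic per-atom jitter (expected RMSF
  $\sqrt{3}\sigma$) with an optional planted collective mode. The mode is
  projected orthogonal to the 6 rigid-body motions of the base structure
  (`remove_rigid_modes`) before use — otherwise superposition fitting
  absorbs part of it and PC1 cannot recover the planted direction.

## 8. Reproducibility and the CLI

All stochastic stages (K-means restarts, Monte-Carlo searches, generators,
Silhouette subsampling) draw from explicit seeds; per-frame and per-k
substreams are derived with an integer mix kept below 2³¹. Package
functions never leak RNG state. The CLI (`pd_cli()`, wrapper in
`inst/scripts/pocketdyn`) writes a `run_record.json` per run with command,
parameters, input digests, seeds and version; the record carries a
wall-clock timestamp, so end-to-end determinism is defined (and tested) as
byte-identity of all *data* outputs across reruns with the same seeds.

## 9. Known limitations

* XTC trajectories are not readable: the compressed coordinate codec has
  no R implementation, and the package deliberately does not vendor one.
  DCD, multi-model PDB and GRO cover the binary and text paths.
* The accession-based sequence comparison (49 % identity / 65 % similarity
  between the mosquito and mouse enzymes) needs the two chain sequences as
  input; offline environments cannot fetch them, and the alignment
  convention (Needleman–Wunsch, BLOSUM62, gap 10/0.5, percentages over
  alignment columns) is itself a documented choice since the source does
  not state one.
* GRO round trips are exact only to the format's 0.001 nm grid (0.01 Å).
* The gorge profiler assumes a straight axis; strongly curved channels
  need full 3-D pore tracing, which is out of scope.
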