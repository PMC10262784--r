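---
title: "Comparative trajectory analysis with mdtk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative trajectory analysis with mdtk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mdtk` analyzes molecular-dynamics trajectories of two-chain protein
complexes and compares two trajectories run under identical settings. The
motivating use case is a kinase–substrate system in which a kinase variant
is suspected of rigidifying the fold and steering the bound substrate toward
a minor conformation (for ubiquitin-family substrates, a C-terminally
retracted state with a better-exposed phosphoacceptor serine). This
vignette documents the methods, the parameters that matter, the synthetic
ground-truth generator, the numerical conventions, and the limitations.

## The analysis pipeline

`run_analysis()` executes, per trajectory and in this order: load → align →
RMSD/RMSF → residue-motion covariance → secondary-structure timeline and
occupancy → substrate-residue SASA, buried surface area and retraction
distance (each with a moving average) → hydrogen-bond counts → pairwise
RMSD → Quality-Threshold clustering with reference labeling → weighted
energetics. For two trajectories it adds a delta block. Every stage is
deterministic given the configuration, and the resolved settings (with a
`source` tag saying whether each default is a literature convention or an
artifact choice) are echoed into every report, so a result can always be
traced to its exact settings.

### Superposition and fluctuations

Frames are superposed onto a reference frame by weighted Kabsch
superposition: with centered coordinate sets the optimal proper rotation is
obtained from the SVD of the 3×3 weighted covariance, flipping the smallest
singular direction when the unconstrained optimum is a reflection. The fit
is computed on a *fit selection* — by default the kinase-chain backbone
(N, CA, C, O) — and applied to all atoms. Fitting on the rigid chain
matters: fitting on atoms that themselves fluctuate redistributes their
motion into apparent motion of everything else (a 1/N centering effect plus
rotation noise that grows with distance from the fit centroid), which
inflates RMSF and plants spurious covariance. The RMSF of an atom is the
root mean square of its deviation from its mean position over frames;
per-residue values are the mass-weighted mean of the residue's atomic RMSFs
(for CA-only selections the weighting cancels).

### Covariance of residue motions

Each residue is represented by the mass-weighted mean displacement of its
selected atoms; the normalized covariance is
`C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, symmetric with unit
diagonal and entries in [-1, 1]. Residues with zero variance get a zero
row/column (diagonal 1) and a warning rather than NaNs. Whether such
matrices should be built on all heavy atoms or CA only is a genuine
convention split among trajectory tools; `mdtk` fixes the mass-weighted
mean-displacement convention, defaults the pipeline to CA, and echoes the
selection in the report. Partners with `|C| >= 0.75` are reported as highly
significant correlated motions, the conventional threshold.

### Secondary structure

Assignment is DSSP-style: backbone hydrogen bonds are scored with the
Kabsch–Sander electrostatic energy
`E = 0.084 * 332 * (1/r(O..N) + 1/r(C..H) - 1/r(O..H) - 1/r(C..N))`
kcal/mol, with a bond when `E < -0.5`. The amide H is reconstructed when
absent (1.01 Å from N, anti to the bisector of C(prev)→N and CA→N; the
first residue of a chain and prolines get none), so the assigner is fully
defined on heavy-atom trajectories. n-turns (an i→i+3/4/5 bond) yield
3-10/alpha/pi helices when two start consecutively, bridge patterns yield
B and ladders E, turn spans yield T, everything else C, with priority
H > E > B > G > I > T > C. Many trajectory pipelines use STRIDE-based
assignment instead; the Kabsch–Sander energy was chosen here because its
formula is fully published and therefore unit-testable against direct
evaluation — assignments near class boundaries can differ between the two
families of assigners, and reports name the algorithm. Occupancy statistics
come in two modes: `per_residue_mean` (mean over residues of each residue's
fraction of frames in the code set) and `all_residues` (fraction of frames
in which the whole region is simultaneously in the code set); both are
reported because region-level statements ("the tail is a turn X% of the
time") are ambiguous between them.

### Surfaces

SASA uses Shrake–Rupley quadrature: each atom's accessible sphere (radius
`vdw + probe`, probe 1.4 Å) is sampled with a deterministic Fibonacci
lattice (default 960 points, `>= 64` enforced); a point is buried if it
falls inside any neighbor's expanded sphere. The lattice is deterministic
so results carry no RNG state; the residual orientation dependence is below
0.5% at 960 points and halving with point count, which the tests check.
Radii come from a fixed Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å) documented in one place. Buried surface area per frame is
`(SASA_A + SASA_B - SASA_AB)/2`; negative values beyond 1e-6 Å² (possible
only through quadrature noise) are clamped to zero with a warning. The
exposure of the substrate phosphoacceptor is computed as the SASA of *all*
atoms of that residue in the context of the whole complex; a side-chain-only
scope is available through the selection language, and the scope used is
echoed in the report.

### Hydrogen bonds

Detection is geometric: donor and acceptor N/O heavy atoms from a documented
chemistry table (backbone N donor and O acceptor, standard side-chain
roles, no pKa logic), donor–acceptor distance `<= 3.5` Å, and — when the
donor carries a hydrogen — a D–H...A deviation from linearity `<= 30
degrees`. On heavy-atom-only inputs the distance criterion alone applies.
Published trajectory tools differ in their default cutoffs and rarely state
them; both values are configuration-exposed and echoed, and counts between
two selections include both donor→acceptor directions.

### Conformation metrics

Backbone phi/psi follow the IUPAC sign convention; terminal residues get an
explicit undefined-angle flag rather than silent NaN. Ramachandran
proximity to reference conformations uses a wrap-aware metric (Euclidean on
the torus), with a default near-reference radius of 30 degrees — an artifact
convention chosen to be small against the separation of distinct
conformational basins yet large against thermal jitter; it is a reporting
device, not a physical claim. The retraction marker is the CA–CA distance
between the two named residues (46 and 76 by default): which atoms to
measure is genuinely underdetermined in the literature, CA–CA is the least
arbitrary choice, and any atom pair can be configured. Moving averages use
a centered window of `round(window/frame_dt)` frames forced odd, truncated
at the edges, so a 5-nsec window on 250-psec frames averages 21 frames and
the output length equals the input length.

### Clustering and energetics

The pairwise frame-to-frame RMSD matrix uses a fresh Kabsch superposition
per pair, making the metric rigid-motion-free; memory is quadratic in
frames and a stride option subsamples long trajectories (6,000 frames at
250 psec/frame is the scale of a 1.5-µsec run; its full matrix is ~275 MB).
Quality-Threshold clustering grows, for every unassigned frame as candidate
seed, the set of unassigned frames within the cutoff *of the seed* (not the
pairwise diameter — the common trajectory-clustering semantics; the
alternative is stricter and yields smaller clusters), commits the largest
candidate with ties to the lowest seed index, and stops when the largest
candidate falls below the minimum cluster size (default 1% of frames).
Frames left over are rejected; a rejection rate above 5% warns, the
conventional quality bar. The default cutoff of 1.75 Å is the conventional
heuristic for substrate-scale conformational sorting and should be re-tuned
per system. Cluster centers minimize the summed RMSD to their members and
are labeled by the nearest reference structure under Kabsch RMSD with
residue pairing.

Energetics weight per-cluster interaction energies by the fraction of *all*
frames the cluster represents — rejected frames dilute the total rather
than being renormalized away, because the weight is meant to be "fraction
of simulation time in this conformation". The built-in scorer is a
deliberately simple contact count (`-epsilon` per inter-chain heavy-atom
pair within 4.5 Å): deterministic, linear, and exactly testable, but
explicitly non-physical. Production energetics should use the provider
interface, which accepts per-cluster energies computed by any external
force-field scorer.

## The synthetic generator

Microsecond trajectories of real complexes are far too large to ship, so
the package carries a generator whose outputs have *known* statistics:

* `simulate_trajectory()` draws iid Gaussian per-residue rigid
  displacements about a base structure. The planted amplitude is defined as
  the target RMSF (per-axis sd `a/sqrt(3)`), inter-residue correlations are
  enforced through a latent-factor decomposition of the implied correlation
  matrix (validated positive semi-definite before sampling), and an
  optional per-frame global rotation/translation exercises the alignment
  stage.
* `simulate_two_state()` mixes two conformers at a stated occupancy (iid
  frames, or a two-state Markov chain with a stated mean dwell) plus
  Gaussian jitter, recording the realized state sequence.
* `synthetic_study_pair()` packages the full demonstration: a
  kinase-analog helix docked against a substrate whose "common" conformer
  has an extended tail and an interface-buried residue 65, and whose
  "retracted" conformer folds the 63–76 arm back (hinge at 60–62) and
  closes the tail with a type-I beta turn. Every comparative contrast
  therefore has a planted direction: the mostly-retracted, low-jitter
  "variant" run must show lower RMSF, shorter 46–76 distance, higher
  residue-65 SASA, higher tail-turn occupancy, and higher retracted-cluster
  frequency than the mostly-common, high-jitter "wt" run.

Frames are independent draws — there are no forces, solvent, or kinetics —
so passing tests demonstrate that the *analyses* recover planted statistics,
not that the generator resembles physical dynamics. Real trajectories add
temporal correlation (slower convergence of every estimator), anharmonic
and multi-basin motions beyond two states, and solvent effects on surfaces;
occupancy percentages measured on real systems cannot be reproduced from
this package alone.

## Numerical conventions and test sizes

Seeds make every generator bitwise reproducible (the RNG state is restored
afterwards). Degenerate inputs fail loudly: superposition of fewer than 3
or collinear points, empty selections, zero-variance residues, unpairable
reference residues, windows shorter than a frame. Tie-breaks are fixed and
documented (QT seed and center ties to the lowest index; altloc ties to
first encountered).

The test and acceptance workloads use sizes chosen to make sampling bounds
sharp at desk scale: 5,000 frames for amplitude/correlation/occupancy
recovery (binomial error ~0.006 on an occupancy of 0.3), 1,000 random rigid
motions for superposition recovery, 100 random 50-frame instances for the
QT brute-force equivalence, and a 300-frame two-trajectory study for the
end-to-end comparison. The independent oracles are a 10^5–10^6-point
Monte-Carlo surface sampler, a multi-start numerical rigid-fit optimizer, an
exhaustive QT re-enumeration, direct evaluation of the Kabsch–Sander
energy, and all-pairs contact counting.

## Limitations

* PDB is the only trajectory format (no mmCIF/DCD/XTC); the reader is the
  adapter point.
* No principal-component or normal-mode analysis; no chi side-chain
  dihedrals; no salt-bridge or pi-interaction detection.
* The contact scorer is a stand-in; weighted totals built on it are only
  meaningful for ranking within one system, and real energetics should come
  through the provider interface.
* Quadratic pairwise-RMSD memory (mitigated by `stride`).
* The bundled references for cluster labeling are synthetic stand-ins;
  users comparing against crystallographic conformers should supply their
  own reference PDBs.
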