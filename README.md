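# mdtk — comparative analysis of MD trajectories of kinase–substrate complexes

`mdtk` is an R toolkit for the comparative analysis of molecular-dynamics
trajectories of two-chain protein complexes. It was built around a recurring
question in kinase biology — does a stabilizing kinase variant shift a bound
substrate (e.g. ubiquitin bound to PINK1) toward a minor conformation such as
the C-terminally retracted state that better exposes its phosphoacceptor
serine? — but every stage is generic: any multi-model PDB trajectory of a
two-chain complex can be analyzed and two trajectories compared under
identical settings.

The package implements, with tests against independent oracles:

* **Multi-model PDB I/O** with an atom-selection mini-language, element
  masses and a fixed Bondi-style van der Waals radius set.
* **Weighted Kabsch superposition** (proper rotation by SVD with reflection
  correction), trajectory alignment, per-frame RMSD and per-residue RMSF.
* **Mass-weighted normalized covariance** of residue motions,
  `C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, with thresholded
  extraction of highly correlated partner residues (|C| >= 0.75).
* **Secondary structure** per frame via a DSSP-style assigner using the
  Kabsch–Sander hydrogen-bond energy
  `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
  (bond if E < -0.5), plus occupancy statistics over residue regions.
* **Shrake–Rupley SASA** on a deterministic Fibonacci point lattice
  (probe 1.4 Å) and per-frame **buried surface area**
  `BSA = (SASA_A + SASA_B - SASA_AB) / 2`.
* **Geometric hydrogen-bond counting** between selections
  (donor–acceptor <= 3.5 Å, D–H...A within 30° of linear when H is present).
* **Ramachandran distributions** with wrap-aware proximity to reference
  conformations, inter-residue **distance series** (e.g. the Ala46–Gly76
  retraction marker of ubiquitin), and centered **moving averages**.
* **Quality-Threshold clustering** of the pairwise Kabsch RMSD matrix
  (cutoff to the candidate seed; largest candidate committed each round),
  cluster centers, and nearest-reference labeling of each center.
* **Cluster-frequency-weighted interaction energetics**
  `dG_total = sum_i dG_i * f_i`, with a deterministic contact-count stand-in
  scorer and a provider interface for externally computed per-cluster
  energies.
* A **synthetic trajectory generator** that plants per-residue fluctuation
  amplitudes, inter-residue correlations, and two-state conformational
  mixtures with stated occupancies, so every analysis stage has exact ground
  truth.

## Selection mini-language

Clauses combine with `and` / `or` (`and` binds tighter) and parentheses:

| clause            | meaning                                             |
|-------------------|-----------------------------------------------------|
| `chain <id>`      | atoms of a chain, e.g. `chain U`                    |
| `resid <a>[-<b>]` | author residue numbers; values and inclusive ranges |
| `name <n1> ...`   | atom names, e.g. `name CA` or `name N CA C O`       |
| `backbone`        | shorthand for `name N CA C O`                       |
| `all`             | every atom                                          |

Example: `chain U and resid 46-76 and name CA`.

## Worked example

The packaged synthetic study simulates a substrate exchanging between a
"common" and a retracted ("cr") conformation under two regimes: a flexible
mostly-common *wt* and a stabilized mostly-retracted *variant*:

```r
library(mdtk)
pair <- synthetic_study_pair(n_frames = 60, seed = 42)
cfg <- validate_config(list(
  trajectory   = pair$traj_wt,
  trajectory_2 = pair$traj_variant,
  ref_common   = pair$state_common,
  ref_cr       = pair$state_cr))
report <- run_analysis(cfg)
print(report)
#> comparison_report
#>               metric trajectory_1 trajectory_2    delta
#>     mean_rmsf_kinase        0.342      0.16980  -0.1722
#>  mean_rmsf_substrate        4.189      1.56542  -2.6233
#>        mean_sasa_s65       53.565     59.04443   5.4791
#>             mean_bsa       25.087      1.37228 -23.7144
#>      mean_retraction       39.394     32.97350  -6.4210
#>          mean_hbonds        0.000      0.00000   0.0000
#>  tail_turn_occupancy       13.333     43.33333  30.0000
#>           n_clusters        2.000      2.00000   0.0000
#>    cr_like_frequency        0.400      0.96667   0.5667
#>          weighted_dG       -0.420     -0.01333   0.4067
```

Reading the deltas (trajectory 2 minus trajectory 1): the variant complex
fluctuates less (lower kinase and substrate RMSF), its substrate spends far
more time in retracted-like clusters (`cr_like_frequency` 0.97 vs 0.40),
its 46–76 retraction distance is ~6 Å shorter, residue 65 is ~5 Å² more
solvent-exposed, and the C-terminal tail codes as turn three times more
often — the full signature of a substrate driven toward the retracted
conformation. The clustering and energetics behind those numbers:

```r
print(report$bundle_2$clusters)
#> cluster_set: 2 clusters over 60 frames (cutoff 1.75 A); rejection rate 0.00%
#>    1:    58 frames (96.7%), center frame 23
#>    2:     2 frames (3.3%), center frame 21
print(report$bundle_2$energetics)
#> weighted_energy_report (provider: contact_count)
#>  cluster  raw frequency weighted
#>        1  0.0     96.7%  0.00000
#>        2 -0.4      3.3% -0.01333
#> total weighted dG: -0.0133 kcal/mol
```

`write_report(report, "out/")` serializes every series, matrix, timeline and
table as TSV. A thin command-line wrapper with `generate` / `analyze` /
`compare` subcommands lives at `inst/scripts/mdtk.R`.

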