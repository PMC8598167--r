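---
title: "Local chromatin fiber folding: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local chromatin fiber folding: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the coarse-grained
chromatin model and its Monte Carlo sampler, the Micro-C style contact
statistics, the erosion diameter estimator, what the synthetic-data
generators do and do not emulate, and the numerical and design choices made
where more than one defensible option existed.

## The question the workflow addresses

Chromatin in quiescent (non-dividing) yeast cells is strongly deacetylated
and enriched for linker histone, and its nucleosome-resolution contact maps
shift mass from immediate-neighbor (n+1) ligations toward the 500–1000 bp
band — the population signature of a *locally folded* fiber, as opposed to
the extended, n+1-dominated fiber of exponentially growing cells. The
workflow in `analysis/` reproduces the computational side of that
comparison end to end on synthetic data: simulate fibers for the two
chromatin states, measure their compaction, and push synthetic contact
pairs through the same analytics used on sequencing data.

## The mesoscale fiber model

A fiber is a flat list of coarse-grained beads (`build_initial_fiber()`):

* **Nucleosome cores** are rigid bodies: a center bead plus 48 surface
  charge beads on three rings of a cylinder (radius 5 nm, half-height
  2.2 nm). Cores move only through pivot moves, so the surface beads stay
  rigidly attached by construction.
* **Linker DNA** is a bead-spring worm-like chain, one bead per ~9 bp
  (segment length 3 nm). Stretching is harmonic (`stretch_h`, 100
  kBT/nm²); bending is harmonic in the angle with constant
  `g = Lp / l0` in kBT (persistence length 50 nm, or 30 nm in Mg mode);
  each DNA segment carries a scalar twist register with torsional
  persistence 75 nm and a set point at the B-twist offset (−12°, 0° or
  +12°) drawn per trajectory.
* **Histone tails**: two copies each of H3, H4, H2A-N, H2A-C and H2B per
  core, five residues per bead (5/5/3/2/5 beads per copy), attached at
  fixed surface anchors. Tails are flexible chains with their own
  (weaker) stretch and bend constants.
* **Linker histones** on LH-flagged cores: a 6-bead globular domain plus a
  22-bead (H1e) or 21-bead (H1c) C-terminal domain, modeled as a single
  positively charged chain anchored near the dyad.

Nonbonded interactions are Debye–Hückel screened electrostatics
(`lB q_i q_j exp(-κr)/r`, κ = 1.27 nm⁻¹ at 150 mM monovalent salt,
293 K) and 12-6 Lennard-Jones excluded volume with a small well depth
(0.001 kBT), both cut off at 7 nm. Mg²⁺ is treated phenomenologically:
the DNA persistence length drops from 50 to 30 nm and DNA–DNA pairs are
screened with a raised inverse Debye length (`kappa_dd` = 2.5 nm⁻¹).

**Acetylation.** Acetylated tails are modeled *folded and rigid*: their
bonded constants are multiplied by 100, their coordinates snap to a
compact template hugging the core surface, and they are excluded from every
nonbonded pair list ("folded tails do not interact"). The fold state is
sampled by a dedicated swap move (below). In this package the acetylation
flag of a nucleosome folds its four H3/H4 tails: those tails are the
dominant internucleosome bridgers (the H4 basic patch in particular), which
is what makes fiber-scale compaction sensitive to acetylation.

**Charges are stand-ins, calibrated once.** The published mesoscale
family derives core surface charges from an atomistic charge-optimization
procedure that is out of scope here. This package instead exposes
per-bead charges in `force_field()`: DNA −7 e/bead
(counterion-condensation scale), core surface −3 e/bead, H3/H4 tails
+2.8 e/bead versus +1.0 e/bead for the H2A/H2B tails (the H3/H4 tails,
and the H4 basic patch in particular, are the dominant internucleosome
bridgers), LH +5.5 e/bead. These values were calibrated on the model
itself — not on any published number — so that the fiber sits near its
folding transition: a composition with every tail active and abundant LH
folds reliably within a desk-scale run, while removing the H3/H4 glue
from the acetylated fraction of nucleosomes leaves the fiber partially
extended. Near the transition the *composition* of the fiber, rather
than saturated attraction, controls compaction, which is exactly the
regime the log-versus-quiescence comparison probes. Absolute energies
and compaction magnitudes should therefore not be over-interpreted; the
assertable quantity is the direction of the contrast.

**Linker histone geometry.** The LH C-terminal domain is modeled as a
*compact* charged blob (0.6 nm bonds) anchored at the dyad rather than an
extended 40 nm chain: in a model without explicit stem geometry, an
extended highly charged CTD acts as a polymer brush that sterically
*blocks* nucleosome approach and competes with tails for core surfaces —
the opposite of the compacting role LH plays in chromatin. The compact
blob instead adds a localized positive patch that bridges linker DNA and
neighboring nucleosomes. An LH's binding to its *own* nucleosome is
carried by its anchor tether (the chromatosome), so LH beads are excluded
from nonbonded interactions with their own core's charge beads, exactly
as linker DNA beads are excluded from the charge beads of the core whose
wrapped DNA they continue.

### Initial configuration

Simulations start from an ideal two-start zigzag (alternating ±6 nm lateral
offset, 7 nm rise per nucleosome) with linker beads threaded along a
straight or gently bowed path between consecutive cores. The zigzag is
deliberately open: no two decorated cores interpenetrate at step zero, so
early dynamics relax strain instead of resolving hard overlaps. Linker DNA
beads do not interact with the charge beads of the core that owns them
(each half-linker belongs to its nearer core) — the linker is continuous
with that nucleosome's wrapped DNA, and letting them repel would put a
spurious barrier right at the DNA exit point.

## Monte Carlo sampling

Five tailored moves (`move_schedule()`, compiled inner loop in
`run_trajectory()`):

1. **Pivot** (global): a random position along the fiber path bisects the
   chain; the side with fewer path beads — ties go to the lower-index
   side — rotates rigidly about a random axis through that point.
   Metropolis acceptance on the cross-side nonbonded energy plus the
   bonded terms spanning the cut.
2. **Translate** (local): one uniformly chosen DNA or LH bead moves within
   a cube of half-width `amp_translate`.
3. **Rotate** (local): one DNA segment's twist register is perturbed. In
   this register formulation twist decouples from bead positions — a
   deliberate simplification that keeps the twist thermodynamics exact
   while leaving twist-bend coupling out of scope.
4. **Tail regrowth** (configurational-bias): a random *unfolded* tail is
   regrown bead by bead from the core outward with k trial positions per
   bead (default 8). Trial bond lengths are drawn from the full internal
   Boltzmann density (Gaussian proposal with an l² Jacobian rejection), so
   trial weights carry only external energy and the Rosenbluth acceptance
   `min(1, W_new/W_old)` is exact; in zero field every regrowth accepts.
5. **Fold swap**: a random acetylation-flagged tail exchanges coordinates
   and equilibrium constants with its stored alternate template; exact
   involution, Metropolis acceptance.

The default mixture 0.2/0.3/0.2/0.2/0.1 with amplitudes 25°, 0.4 nm and
20° lands in the conventional 30–50% acceptance window on desk-scale
fibers (the original study does not state its mixture, so these are this
package's own defaults, all configurable). Each trajectory owns one
seeded generator; reruns are bit-identical, and no global RNG state is
touched.

**Desk scale.** The production scale of the original analysis — 50
trajectories of ≥6×10⁷ steps on 222/228-nucleosome fibers — is far beyond
an interactive session. The workflow and the test suite run 12-nucleosome
fibers for 5×10⁵ steps and 3 seeds per state (roughly a minute per
trajectory), which is enough to observe compaction contrasts beyond
pooled across-seed error but not to claim converged absolute values.
Analyses of scalar statistics use the final sixth of each trajectory,
mirroring the production rule of analyzing the last 10⁷ of 6×10⁷ steps;
contact and tail statistics use the whole run at their own cadences
(default 10⁴ and 10⁵ steps), as in the original analysis.

## Fiber statistics

* `sedimentation_coefficient()` implements
  `S = [S1 + (S0−S1)·LH_conc] · (1 + (R1/N_C) ΣΣ 1/R_ij)` with S0 = 12 S
  (mononucleosome with LH), S1 = 11.1 S (without), R1 = 5.5 nm, the double
  sum over ordered pairs. The printed form of this relation is
  typographically ambiguous; this grouping is the unique one that
  reproduces both mononucleosome limits exactly, and `LH_conc` defaults to
  the fiber's own flagged fraction.
* `radius_of_gyration()` is the RMS distance of core centers from their
  mean.
* `packing_ratio()` is `11 · N_C / fiber length`, the fiber axis being a
  cubic smoothing spline through the core centers versus fiber index
  (`spar` exposed; 0 interpolates).
* `fiber_volume()` is the alpha-shape volume of the core centers
  (`alpha = Inf` gives the convex hull), built on an internal
  Bowyer–Watson tetrahedralization with a deterministic 10⁻⁸-relative
  jitter to break cospherical ties.
* `cluster_nucleosomes()` is density-based clustering with a 20 nm
  neighborhood and a 3-neighbor core rule; no clustering package ships in
  this stack, so the ~40-line standard algorithm is implemented here and
  cross-checked in the tests against an independent connected-components
  formulation.
* `internucleosome_contact_map()` marks nucleosomes i, j in contact when
  any tail or charge bead of i is within 2 nm of one of j (folded tails
  excluded), accumulates binary contacts at the recording cadence,
  normalizes each trajectory's count matrix by its maximal entry (a
  scalar — per-element normalization would destroy the relative
  intensities that the neighbor profile depends on), and sums across
  trajectories. `neighbor_profile()` projects the map to I(k), normalized
  to unit sum.
* `tail_interaction_matrix()` assigns each unfolded tail, per sampled
  configuration, to at most one separate-nucleosome element class (core
  charge beads, linker DNA, tails) — the nearest class, and only below
  2 nm. T′ holds occurrence fractions; T row-normalizes them, so nonzero
  rows sum to one. "Separate DNA" excludes the tail's own nucleosome's
  half-linkers. Zero rows are reported as NA, not 0/0.

## Micro-C contact analytics

Pairs are canonically ordered; orientation follows from the strand pair
(`+/−` in-facing, `−/+` out-facing, `++`/`−−` tandem — the "same" class).
In-facing pairs, the signature of undigested di-nucleosomes, are dropped.
Binning floors `(pos−1)/bin` at 10, 200 and 5000 bp. Decay curves divide
each 10 bp diagonal's total by the number of elements in that diagonal and
normalize to unit sum (pooled genome-wide by default; per-chromosome
behind an option). The odds ratio divides cumulative probability in
[500, 1000) bp by [50, 500) bp — half-open bands, so the 500 bp stratum is
counted exactly once. Pileups aggregate 20 kb windows centered on anchors
by element-wise median (even counts average the two central order
statistics); inter-anchor pileups use same-chromosome anchor pairs. The
SCC normalizes each matrix by its total, optionally smooths with a
(2h+1)² mean filter (h = 1 bin by default; the reference description
leaves h unstated), computes per-stratum Pearson correlations up to 100 kb
weighted by `N_d · sqrt(var_d(x) var_d(y))`, and reports per-chromosome
values and their median. Zero-variance strata carry zero weight.

## Erosion diameter estimation

`erosion_profile()` erodes a binary volume with discrete Euclidean balls of
increasing radius and records the residual volume fraction. It is computed
via a single exact Euclidean distance transform — a foreground voxel
survives erosion by radius r exactly when its squared distance to the
nearest background voxel exceeds r² — so the whole profile costs one
O(N) transform. Out-of-array voxels count as foreground (replicate
padding), so a tube crossing the volume erodes radially without end
artifacts. `estimate_diameter()` fits a least-squares line through the
first five points starting at the smallest *nonzero* radius (radius zero
carries no slope information) and reports the x-intercept in nm. For an
ideal cylinder of radius R the residual fraction falls as (1−r/R)², so
the small-radius linear extrapolation intercepts near R/2, not at the
diameter; the estimator therefore reports the raw intercept together with
a calibration factor measured on synthetic cylinders
(`erosion_calibration()`), and makes no absolute-diameter claim for other
shapes. Ratios between estimates track ratios of true diameters to within
a few percent when the radii stay well inside the tube radius, which is
why the workflow probes 20–40 nm tubes at 0.5 nm voxels with radii 1–5.

## Synthetic data: what it does and does not emulate

* **Tracks** emulate MNase-seq nucleosome calls plus ChIP-seq flag calls:
  ~165 bp repeat with jitter (floored at the 147 bp core footprint),
  optional nucleosome-free gaps, Bernoulli acetylation/LH flags at the
  published densities (log: 61/222 acetylated, 0.05 LH/nucleosome;
  quiescent: 3/228, 0.29). Not emulated: sequence-dependent positioning,
  fuzzy/overlapping calls, flag autocorrelation along the fiber.
* **Pairs** draw genomic distances from an explicit mixture: neighbor
  modes at k×repeat (the units the decay analysis plots), a long-range
  band, uniform background, optional anchor loops and stripes; strands are
  emitted so a configured fraction is in-facing, the remainder split
  evenly across out-facing and both tandem orientations (every class must
  be populated because the analysis stratifies by orientation). The
  log-like preset is n+1-dominated; the quiescent-like preset moves mass
  into 500–1000 bp. For analyses that need reproducible *positional*
  structure at the 5–100 kb scale (pileups, the SCC), each state gets its
  own anchor set with loops and stripes — prominent in the quiescent-like
  samples (condensin-anchored loop domains) and weak in the log-like ones;
  replicates share their state's anchors, so replicate SCCs are high while
  cross-state SCCs are low. The empirical distance distribution beyond
  1 kb of real samples is not published in a parameterized form, so the
  background and long-band knobs are free parameters, not calibrated
  fits — pipeline tests assert recovery of configured mixtures and the
  direction of the odds-ratio contrast, never absolute decay shapes of
  real chromatin.
* **Volumes** are solid cylinders with optional salt-and-pepper noise —
  a geometry fixture, not a simulated tomogram (no missing wedge, no
  stain texture, no segmentation errors).

Passing tests on these generators therefore demonstrate correctness of the
*computations* and the directional signatures built into the presets; they
do not validate the force field against experimental compaction values,
which would require the production-scale runs and deposited data.

## Numerical choices and degenerate inputs

* Energies are in kBT at the configured temperature, lengths in nm, so
  Metropolis exponentials are unit-free.
* Coordinates are 0-based half-open internally for binning; pair files are
  written 1-based in the pairs text dialect.
* Coincident cores (R_ij = 0), all-zero contact maps, zero-variance SCC
  strata, zero short-range odds mass, empty erosion foregrounds and
  too-short convergence windows all fail loudly or are flagged
  `undefined`/`insufficient` rather than returning silent zeros.
* The Delaunay-based volume errors out on coplanar point sets; the
  deterministic jitter only breaks *cospherical* ties.
* Trajectory runs abort (with the last valid state retained) if the total
  energy ever becomes non-finite.

## Known limitations

* The force field is a stand-in parameterization; absolute energies,
  sedimentation values and packing ratios from desk-scale runs are not
  comparable to published production-scale numbers — only directions and
  internal contrasts are.
* Twist is a per-segment register decoupled from bead geometry; there is
  no twist-bend coupling and no supercoiling transport along the fiber.
* Cores are rigid and identical; no nucleosome breathing, unwrapping or
  heterogeneous DNA wrapping.
* The SCC here follows the straightforward variance-weighted stratum
  correlation on smoothed, total-normalized matrices; rank-based variance
  stabilization used by some implementations is not included.
* Inter-chromosomal pileups and matrix balancing are out of scope (raw
  counts are the analysis currency throughout).
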