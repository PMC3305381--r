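---
title: "Trajectory-ensemble analysis of allosteric coupling with allodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-ensemble analysis of allosteric coupling with allodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

## The problem

Allosteric proteins transmit the effect of ligand binding at one site to
a distant site. A classic example is the KIX domain of the
transcriptional coactivator CBP: it carries two separate binding
grooves, one for MLL-type activation domains and one for c-Myb, and
occupancy of the MLL groove raises the affinity of the c-Myb groove even
though the two surfaces share no direct contact. Two complementary
signatures of such coupling can be read from conformational ensembles of
the domain in its different liganded states:

1. **Correlated fluctuations.** If residue fluctuations in the loop
   between the first two helices are statistically coupled to
   fluctuations in the third helix, the two regions form a communication
   pathway. This is quantified by cross-correlation maps of Cartesian
   and dihedral-angle fluctuations.
2. **Population shifts.** If the conformers that dominate the
   fully-bound ternary ensemble are already visited by the apo or
   singly-bound ensembles, binding works by re-weighting pre-existing
   sub-states rather than inducing new ones. This is quantified by
   clustering the merged labeled ensembles and measuring how much of
   each state's population falls into clusters occupied by a reference
   state.

allodyn implements both signatures as a reusable pipeline over
single-chain backbone ensembles (multi-model PDB, one MODEL per frame),
together with a synthetic-ensemble generator whose statistics are known
in closed form, so that every stage of the pipeline can be validated
against an analytic oracle.

## Per-state statistics

**Superposition and RMSD.** All comparisons operate on CA atoms with
uniform weights. `kabsch_superpose()` computes the proper rotation
(reflections excluded) minimizing CA RMSD via the SVD of the 3x3
covariance of the centered point sets; degenerate selections (fewer than
3 points, collinear points) are hard errors because the minimizer is not
unique there. `rmsd_series()` reports per-frame minimized RMSD to a
reference, or fixed-frame deviations with `superpose = FALSE`.

**Equilibration.** Ensemble statistics exclude an initial equilibration
segment identified from the RMSD trend. `detect_equilibration()` scans
for the earliest window (default length: 10% of the trajectory) whose
least-squares slope is at most `slope_tol` (default 1e-3 Angstrom/frame)
and whose standard deviation is at most `sd_tol` (default 0.1 Angstrom).
Both tolerances are in the natural units of the series, and both
conditions must hold: the slope test rejects drifting segments, the
spread test rejects noisy transients. A series that never settles
returns its last index with a `converged = FALSE` attribute and a
warning rather than failing, because downstream code may still want the
diagnostic. Fixed per-state equilibration indices can be pinned in the
pipeline configuration instead.

**RMSF.** `rmsf()` is the root-mean-square deviation of each residue's
CA about its position in the average structure, over post-equilibration
frames of an aligned ensemble. When no average is supplied, the
ensemble's own frame mean is used, which makes the mean squared RMSF
exactly equal to the mean squared (fixed-frame) RMSD to the mean - a
Parseval-type identity the test suite checks to 1e-9.

**Torsions.** `torsion_series()` computes phi, psi, or the CA
pseudo-dihedral (the torsion of four consecutive CA atoms of the
virtual-bond trace) per frame, in degrees, range (-180, 180], IUPAC sign
convention. The convention is pinned by a test against an independent
implementation (bio3d).

## Correlation maps

The Cartesian map is the normalized covariance of CA positional
fluctuations,

    C_ij = <dR_i . dR_j> / sqrt(<|dR_i|^2> <|dR_j|^2>),

with averages over post-equilibration frames of an ensemble aligned to
the reference structure. By default `dR_i` is measured about the
trajectory mean, which makes `C` a true correlation matrix with
`<dR> = 0` exactly; `center = "reference"` instead measures deviations
from the reference coordinates (the normalization then uses raw second
moments, so symmetry and the unit diagonal are preserved either way).
Residues with vanishing fluctuation variance (below 1e-12 squared
Angstrom) are an error by name, since their normalization is undefined.

The angular map applies the same normalized form to torsion
fluctuations. Torsion angles live on a circle, and a trajectory
oscillating across the +-180 seam would decorrelate from itself if the
raw values were used. Each torsion is therefore unwrapped first: angles
are mapped to the representative within 180 degrees of the torsion's
circular mean, and fluctuations are linear deviations from that
circular mean. This is the one place the implementation adds a
convention the plain formula does not specify; `unwrap = FALSE`
restores raw-angle behavior for comparison.

Every map constructor asserts the structural contract - symmetric to
1e-12, unit diagonal, entries in [-1, 1] - on every call.

`region_coupling()` condenses a map block into the mean (and mean
absolute) entry over all residue pairs bridging two disjoint regions;
`difference_map()` contrasts two maps of identical kind and labels
entrywise, for wild-type-versus-mutant comparisons.

### Alignment and soft modes

One numerical subtlety deserves emphasis. The synthetic generator draws
frames directly in the reference coordinate frame - no global rotation
or translation is added - so its ensembles are aligned by construction.
Re-fitting each sampled frame onto the reference by Kabsch superposition
is *not* a no-op: the fit removes the best rigid-body approximation of
each frame's genuine internal displacement, and for soft collective
modes (which overlap strongly with rigid rotations) this systematically
distorts the recovered correlations. On a 60-residue chain at 5000
frames we measure a maximum map error of about 0.39 with per-frame
re-fitting versus about 0.022 without. The oracle-recovery tests and the
acceptance script therefore compute the map on the generated ensemble
as-is. For real trajectory data, which arrives in an arbitrary lab
frame, alignment to the reference remains a required step, and the
rigid-motion invariance of the resulting map is itself a tested
property: applying one global rigid motion to all frames and re-aligning
reproduces the map to 1e-9.

## Clustering and ensemble overlap

`combinatorial_cluster()` pools the post-equilibration frames of all
labeled ensembles (pre-aligned to a common average structure) and
k-means-clusters them in CA coordinate space over a residue selection,
with the CA RMSD between conformations as the similarity measure. k is
not chosen by the user: it grows from 1 until every frame lies within
`radius` of its own cluster center, the fixed-radius semantic of
kclust-style conformational clustering. Initial centers come from
deterministic farthest-point seeding (first point drawn from the given
seed), refined by Lloyd iterations to assignment convergence (at most
200 iterations); assignment ties break to the lowest cluster id and an
emptied cluster keeps its center, so the whole procedure is
bit-reproducible given input and seed. Because the per-k clusterings are
shared across thresholds, the cluster count reported by `sweep_radius()`
is non-increasing in the radius by construction.

The default radius is 2.75 Angstrom with a sweep grid of 1.5-4.0
Angstrom: at substantially larger radii distinct conformers merge into
one cluster, at substantially smaller radii within-conformer noise
fragments. The default selection for the RMSD metric
(`kix_binding_site_selection()`) is the union of the MLL-binding and
c-Myb-binding groove residues of KIX; restricting the metric to
functionally important residues makes the clusters discriminate binding-
relevant conformational states rather than loop noise. This list is a
documented package choice, as is the `kix_core_selection()` preset (the
three helices) used for reference RMSD, on the grounds that the mobile
loop should not dominate a "core" deviation measure.

`overlap_report()` turns the cluster occupancy table into population
overlaps: a cluster *belongs to* reference state R if R's share of the
cluster's members reaches `share_threshold`, and the overlap of query Q
with R is the percentage of Q's frames in clusters belonging to R. The
default threshold 0 counts any reference presence, the most permissive
membership arithmetic; raising it tightens membership and can only lower
overlaps. Overlap is deliberately asymmetric - a state concentrated in
one conformer can be fully contained in a reference that spreads over
many, but not vice versa - which is exactly the asymmetry that
distinguishes conformational-selection scenarios.

## The synthetic generator

The generator stands in for molecular-dynamics trajectories that cannot
be redistributed, and is first-class, tested code. It emulates three
features of real ensembles:

* **Topology.** `build_backbone()` constructs N/CA/C backbones from
  ideal internal coordinates (helix phi/psi = -57/-47, 3-10 helix
  -49/-26, omega = 180, standard bond lengths and angles) with loop
  torsions drawn reproducibly from a small coil set; a CA-CA self-clash
  check (2.5 Angstrom) re-draws loops up to 10 times.
  `kix_topology()` encodes the KIX layout in author numbering
  (chain 586-672; G1 591-594, alpha1 597-611, G2 617-621, alpha2
  623-640, alpha3 646-669, loops between - including the L12 loop
  around Phe612).
* **Harmonic fluctuations with known correlations.** `gnm_build()`
  derives a Gaussian network model from CA contacts within a cutoff
  (default 7.0 Angstrom, common GNM practice). The pseudo-inverse of the
  Kirchhoff matrix gives the exact expected correlation map, and
  `sample_gnm_ensemble()` draws i.i.d. frames whose per-axis CA
  covariance is `scale * pinv`. The scalar GNM was chosen over an
  anisotropic network precisely because its Cartesian correlation matrix
  is known exactly, making it the cleanest oracle for the normalized
  covariance map. The default fluctuation scale in examples and tests,
  0.09 squared Angstrom per axis, puts per-residue RMSF in the
  0.5-1.5 Angstrom range typical of a stable folded domain.
* **Discrete sub-states.** `make_mixture_ensembles()` draws each frame
  from one of several shared conformer centers according to per-state
  weights, plus isotropic per-residue noise (0.5 Angstrom default,
  small against the 10 Angstrom default conformer separation).
  `kix_shift_mixture()` fixes the canonical four-state scenario: the
  ternary-state conformer is visited with probability 0.58 by the apo
  state, 0.99 by the MLL-bound state and 0.47 by the c-Myb-bound state,
  while the ternary state occupies it exclusively. Those weights are the
  study conditions of the population-shift analysis; clustering plus
  overlap must recover them to binomial sampling error
  (about +-1.1 percentage points at 2000 frames per state) and
  reproduce the ordering MLL-bound > apo ~ c-Myb-bound.

Planted couplings use `gnm_add_contacts()` / `perturb_contacts()`:
`kix_allosteric_models()` returns a wild-type-like model with explicit
bridge springs connecting the L12/G2 loop region (606-628) to the
alpha3 region (651-666), and a mutant lacking them. The ideal-geometry
builder produces correct secondary structure but not the folded
three-helix tertiary arrangement, so these tertiary contacts are planted
explicitly rather than found by the distance cutoff; if a particular
loop conformation happens to place a bridge pair within the cutoff, only
the missing springs are added. Removing the bridges strictly lowers the
loop-alpha3 region coupling in the analytic map, and sampled maps
reproduce the contrast.

### What the generator does not emulate

Frames are i.i.d. draws - there is no time correlation, no kinetics, no
solvent, and no forcefield energetics. N and C atoms ride rigidly with
their residue's CA in sampled frames, so dihedral-angle correlations of
GNM samples are not physically meaningful (angular maps are exercised on
constructed and mixture ensembles instead). Passing the recovery tests
therefore demonstrates the correctness of the estimators and of the
pipeline plumbing, not that any particular biological system behaves
this way; conclusions about a real protein require real trajectories.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 5000 frames
for correlation-map recovery on a 60-residue chain, 2000 frames per
state for the four-state overlap scenario, 20000 frames for variance
recovery, 3000 frames for the coupling contrast. These sizes were chosen
so that sampling error sits comfortably inside the stated tolerances
(e.g. the standard error of a correlation entry at 5000 frames is below
0.015) while the whole suite stays fast.

Every source of randomness flows from an explicit integer seed; RNG
state is saved and restored around internal draws. Pipeline outputs
contain no timestamps, so identical configuration and seed reproduce
byte-identical CSV files - asserted as a test.

## Known limitations

* One chain per file; insertion codes rejected; hydrogens and side
  chains ignored (all analyses are backbone/CA-level).
* No mutual-information or time-lagged correlation measures; maps are
  linear correlations only.
* No hierarchical or density-based clustering, and no automatic radius
  selection beyond the sweep instrument.
* The "core" and "functionally important" residue selections are
  documented package presets, not published lists; both are ordinary
  configuration entries and should be overridden when better information
  exists.
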