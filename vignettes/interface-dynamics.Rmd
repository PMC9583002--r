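---
title: "Characterising protein-protein interface dynamics with ifdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising protein-protein interface dynamics with ifdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifdyn)
```

## The problem

A crystal structure shows one conformation of a protein-protein interface.
Simulations show that interfaces are plastic: residue contacts break and
reform, the buried surface fluctuates, and many complexes visit a small
number of long-lived interface *substates* with distinct contact patterns.
`ifdyn` quantifies this plasticity from trajectory snapshots of a two-chain
complex with explicit waters. This vignette explains the underlying models
and definitions, the tunable parameters, the synthetic ground-truth
generator used for validation, and the numerical and design choices made
where several reasonable options existed.

## Input model and assumptions

The unit of analysis is the `Snapshot`: heavy atoms of two protein chains
plus water oxygen positions at one time point, assembled into a
time-ordered `SnapshotSeries` of constant topology. Snapshots are assumed
to be spaced coarsely enough (the conventional choice is 1 ns) that water
positions decorrelate between frames; the package analyses per-snapshot
water *structure* and deliberately avoids water *dynamics* (residence
times, exchange kinetics), which need much finer sampling.

Two assumptions are required of the input and not checked further:

* **Periodic-boundary re-imaging is done upstream.** All distance
  computations are plain Euclidean; each chain must already be whole and
  the complex compact. Trajectory post-processing tools handle this better
  than an analysis library could.
* **Residue numbering is the author numbering** of the source file; the
  package never renumbers, so results can be cross-referenced with
  mutation databases directly.

Waters are recognised by residue name (HOH/WAT/SOL/TIP3/TIP/TIP4/SPC,
case-insensitive) and reduced to their oxygen, the convention used for all
shell and interfacial-water definitions. Hydrogens, when present, are kept
aside solely for hydrogen-bond angle checks. XTC trajectories are not
readable by the underlying I/O layer (`bio3d`); multi-model PDB and
PDB + DCD are supported.

## Definitions and parameters

| Quantity | Definition | Default | Why |
|---|---|---|---|
| Residue contact | min heavy-atom distance, boundary inclusive | 5.0 Å | conventional residue-level interface cutoff |
| H-bond | donor-acceptor ≤ 3.5 Å, H-D-A angle ≤ 30° | 3.5 Å / 30° | common geometric criterion of MD analysis tools |
| ASA | Shrake-Rupley quadrature, water-sized probe | probe 1.4 Å, 960 pts | probe mimics a water molecule; 960 points gives ≤ 2% quadrature error |
| ΔASA | ASA_A + ASA_B − ASA_AB | — | buried surface of the complex |
| Interface regions | relative-ASA thresholds in the two contexts | 25% | Levy's support/core/rim scheme |
| Gap index | 2·gap volume / ΔASA | grid 0.8 Å | shape complementarity; lower is tighter |
| iRMSD | backbone RMSD over interface residues after superposition | 10 Å interface, backbone N/CA/C/O | CAPRI-style convention |
| Shells | first: d_m < 3.4 Å; second: 3.4 ≤ d_m < 5.0 Å | fixed | minima of the water-protein distance histogram for TIP3P-like water; `waterDistanceHistogram()` lets users re-derive them |
| Interfacial water | strictly < 4 Å from heavy atoms of both chains | 4.0 Å | slightly beyond H-bonding distance, capturing bridging positions |
| Hotspot | any single mutation with ΔΔG < −2.0 kcal/mol | −2.0 | conventional hotspot threshold |

All cutoffs are exposed as function arguments and recorded in the pipeline
log, so a run is self-describing.

### Contact typing

The polar/apolar partition of residues is not standardised; the package
default counts ARG, LYS, HIS, ASP, GLU, ASN, GLN, SER, THR, TYR, TRP and
CYS as polar and the remaining eight standard residues as apolar - a plain
physico-chemical grouping (charged or hydrogen-bonding side chains). It is
an argument (`polar_set`) precisely because it is a choice, and unknown
residue names error unless an explicit fallback class is supplied.

### Substate clustering

Snapshot interfaces are compared with the Jaccard index of their contact
sets and clustered with Ward.D2 (`stats::hclust`) on `1 - J`. Two
documented caveats:

* `1 - J` is a metric but **not Euclidean**; Ward.D2 is applied to it
  directly, which is standard practice for contact-set dissimilarities but
  means the "variance" interpretation of Ward heights is approximate.
* Two empty contact sets are treated as **identical** interfaces
  (`J = 1`): a dissociated complex in two consecutive snapshots has the
  same (empty) interface. The alternative convention (`J = 0`) is
  available via `empty_value`.

There is no generic rule for the number of clusters. The package codifies
the qualitative goal - few, long-lived, well-populated substates - in
`suggestNClusters()`: the recommended k is the largest k whose smallest
cluster holds at least 5% of the snapshots and whose number of label
changes along the trajectory stays within 2 per added cluster. Both
thresholds are arguments. The "intra-cluster variance" diagnostic is the
mean within-cluster dissimilarity; it is labelled as such because several
nonequivalent definitions circulate. The principal-coordinate projection
(`stats::cmdscale`) truncates the negative eigenvalues that a non-Euclidean
dissimilarity produces.

Cluster labels are renumbered in order of first appearance along the
trajectory, which makes labellings deterministic and comparable across
runs. Centroids maximise the mean Jaccard similarity to the other members;
ties resolve to the earliest snapshot.

### Per-cluster contact statistics

The contact frequency `F_c(XY)` is the fraction of cluster c's snapshots
containing contact XY. Across-cluster variance uses the **population**
(divide-by-N_c) form: with 2-4 clusters the sample variance would inflate
badly, and the population form keeps the interpretable 0.25 upper bound
for frequencies in [0, 1]. The residue-level map takes the maximum
variance over a residue's contacts, and the recurrence index takes the
within-cluster best partner frequency, minimised over clusters. A residue
with no contact at all in some cluster has an empty partner set there; the
inner maximum is defined as 0, so full absence from a substate drives
recurrence to 0, which is the intended reading of the index.

The hotspot rule is applied exactly as stated above (ΔΔG < −2.0 kcal/mol).
Some mutation databases report destabilising mutations with positive ΔΔG;
rather than silently "correcting" the inequality, `hotspotCrossref()`
exposes `flip_sign` and leaves the direction to the user.

### Released waters

Hydration-shell counts are defined for any single structure, but the
quantity of thermodynamic interest is the *release upon complexation*. The only
combination consistent with a per-complex scalar is

N_released = mean_t N_shell(free A) + mean_t N_shell(free B)
− mean_t N_shell(complex),

with each mean taken over its own trajectory and the standard errors of
the three means combined in quadrature. This estimator requires unbound
trajectories of both partners - one reason the synthetic generator
produces bound and unbound forms with identical per-chain topology.

### Comparing dependent correlations

When the number of released waters and ΔASA are both correlated with the
binding affinity of the *same* complexes, the two coefficients share a
variable and a sample, so comparing them needs the dependent-overlapping
form of the test. `dunnClarkTest()` implements the Dunn-Clark (1969)
back-transformed z statistic, with the intercorrelation r23 entering the
covariance correction. A Monte-Carlo calibration test (trivariate normal
null, n = 50, 2000 replicates) guards the implementation: the empirical
type-I error at α = 0.05 must stay within [0.03, 0.07].

## The synthetic-data generator

Validation needs inputs with known truth; the generator produces three.

**Contact series with hidden substates.** Each substate is a predefined
contact set; the series dwells in each substate for a prescribed number of
snapshots and every contact slot flips independently with probability
`flip_noise` within a finite universe (union of substate sets plus an
optional decoy pool, keeping absent-to-present flips meaningful). This
emulates long-lived, well-populated substates with thermal contact noise.
It does not emulate gradual transitions, autocorrelated noise, or contact
sets that drift within a substate.

**Toy complexes.** Rigid three-atom pseudo-residues on a jittered lattice,
two chains facing across a prescribed `interface_gap`, residue names drawn
from a polar/apolar alphabet so typing is exercised, and waters placed by
rejection sampling with a 2.4 Å clash distance (approximately the sum of
vdW radii minus tolerated overlap). Unbound forms are the isolated chains
far apart with their own waters. These toys make brute-force distance
oracles affordable; they are *not* physically realistic - no force field,
no secondary structure, no realistic packing - so tests on them
demonstrate correctness of the geometry and bookkeeping, not biological
realism.

**Correlated pairs.** Bivariate normal draws with prescribed population
correlation, for exercising the correlation machinery at any n and rho.

All generators are bit-reproducible under a fixed seed.

## Numerical choices

* **ASA.** The Shrake-Rupley quadrature uses a deterministic golden-spiral
  point set; vdW radii are a NACCESS-like protein set (C 1.87, N 1.65,
  O 1.40, S 1.85 Å) and relative ASA normalises by Gly-X-Gly maximal
  exposure values. Absolute areas therefore differ from other ASA engines
  by a few percent; all derived thresholds (interface detection, region
  classes) are designed to tolerate that. Interface membership requires a
  per-residue ASA change above 0.1 Å² to suppress quadrature noise.
* **Region threshold ties.** The three Levy rules use strict inequalities;
  an interface residue at exactly 25% in both contexts satisfies none and
  is assigned to the rim (peripheral catch-all).
* **Gap volume.** The SURFNET-style construction (midpoint spheres shrunk
  to touch the nearest vdW surface, kept for radii in [1, 5] Å, union
  integrated on a 0.8 Å grid) is a documented approximation;
  bit-compatibility with SURFNET is explicitly not claimed. On a planted
  spherical cavity of radius 3 Å the estimate is within 10% of the
  analytic volume.
* **iRMSD reference.** The interface set is defined on the first snapshot
  passed (for trajectory profiles, the first production frame) and is
  configurable; defining the set on a fixed reference makes the measure
  symmetric and comparable along the trajectory.
* **Determinism.** Every stochastic component consumes an explicit seed;
  the pipeline writes tables in a canonical row order and its outputs are
  byte-identical across runs with the same config and seed.

## Validation strategy and problem sizes

The test suite cross-checks every set-based statistic (contacts, Jaccard
matrices, shell counts, interfacial waters, bridges, frequencies, variance,
recurrence) against naive brute-force implementations on small instances
(up to ~12 snapshots and a few tens of residues), checks the analytic
surface identities (isolated sphere, two-sphere closed form, planted
cavity), the Lance-Williams recurrence against `hclust` merge heights, and
the clustering end-to-end on synthetic ground truth: two substates of 150
snapshots each with 5% flip noise are recovered with adjusted Rand index
at least 0.9 in at least 95% of 20 seeds, and the size/stability
diagnostics recommend two clusters. These sizes keep the full suite under
a minute on one core while leaving every code path exercised.

## Known limitations

* No XTC reading, and no periodic-boundary treatment (see assumptions).
* ASA, gap volume and iRMSD are re-implementations, numerically close to
  but not bit-compatible with NACCESS, SURFNET and DockQ.
* Ward.D2 on a non-Euclidean dissimilarity and the empty-set Jaccard
  convention are documented choices, not mathematical necessities.
* Water analyses describe per-snapshot structure only; kinetic quantities
  are out of scope.
* The released-water estimator needs unbound trajectories of both
  partners; without them only per-structure shell counts are available.
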