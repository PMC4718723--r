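---
title: "Covariance-constrained helix tracing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-constrained helix tracing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixtrace)
```

## The problem

At 6–8 Å resolution a cryo-EM map of a membrane protein resolves
trans-membrane α-helices as elongated tubes of density, but neither side
chains nor the connectivity between helices. A backbone model can still be
built if an independent source of spatial information pins down which helix
of the sequence goes into which density rod, pointing which way. Evolutionary
covariance analysis provides exactly that: residue pairs that co-vary across
a deep sequence alignment tend to be close in space, so a list of top-scoring
predicted contacts acts as a set of distance restraints. helixtrace makes
this reasoning explicit, reproducible and testable:

1. build ideal α-helices from backbone dihedrals (`build_ideal_helix()`),
2. detect rod-like density features (`rod_detect()`),
3. search every assignment of helix segments to rods — including direction,
   axial register and roll — for the one that satisfies the most contacts
   (`search_best()`),
4. validate a model by the fraction of top contacts whose Cα–Cα distance is
   below a threshold (`satisfaction()`),
5. compare conformational states by real-space map alignment/averaging
   (`align_maps()`, `average_maps()`, `fsc()`) and rigid-body rotation
   decomposition (`superpose()`, `rotation_angle_axis()`, `ring_offset()`).

The satisfaction statistic is the model-quality currency throughout: a pair
(i, j) is *satisfied* by a model when the Cα–Cα distance is at most the
threshold (default 15 Å, the customary model-checking distance at this
resolution); the headline numbers are the satisfied fraction and the mean
pair distance over resolvable pairs. Pairs whose residues are absent from a
partial model are reported as *unresolved*, never as violations.

## Ideal helix construction

Helices are built residue by residue from internal coordinates with
φ = −57°, ψ = −47°, ω = 180° and standard peptide bond geometry
(N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å; angles 111.2°, 116.2°, 121.7°).
The dihedrals fix the fold; the bond set is a convention recorded in
`helix_params()` so that tests can pin exact coordinates. The resulting
geometry is the canonical α-helix: consecutive Cα–Cα 3.80 Å, rise ≈ 1.5 Å
per residue, ≈ 3.6 residues per turn, Cα radius ≈ 2.3 Å (`helix_stats()`).
Models are poly-alanine backbones; all scoring uses Cα positions only, so
side chains would add nothing here.

## Assignment search

`place_helix()` makes the manual act of fitting a helix into a rod
reproducible: the helix axis is placed on the rod's line, `direction`
chooses which terminus faces which rod end, `register_shift` slides it in
whole-residue rise steps and `roll` spins it about the axis. Helices longer
than their rod overhang symmetrically, because rods detected at a density
threshold underestimate the true helix extent.

`search_best()` enumerates every injective helix-to-rod mapping crossed with
every direction choice (K!·2^K for K helices on K rods; exhaustive up to
K = 8, i.e. ≈ 10^7 evaluations). For each geometric assignment, register and
roll are refined over discrete grids — register −4…+4 residues, 8 roll
angles — by one deterministic forward sweep: all helices start at register 0
and roll 0, then each helix in segment order moves to the grid point that
maximises the number of satisfied pairs, with ties resolved by smaller total
distance, then smaller register, then smaller roll. A joint grid over all
helices would cost (9·8)^K evaluations per assignment and is infeasible; the
one-pass sweep is deterministic, cheap, and in practice recovers the
generating placement (see the recovery experiment below). The same sweep
contract is implemented twice — once in plain R (`score_assignment()`,
rebuilding every model through `place_helix()`) and once in compiled code
behind `search_best()` — and the test suite checks that both routes produce
identical rankings against an independently written brute-force re-scorer.

Solutions are ranked by satisfied pairs (descending), mean pair distance
(ascending), then enumeration order, so results are fully reproducible. The
`unique_maximizer` flag records whether exactly one assignment attains the
maximal satisfied count — the formal version of a fold being determined
"uniquely" by the constraints; mean distance is a tie-breaker, not evidence
of uniqueness. Beyond K = 8 a greedy constructor with swap refinement is
available but clearly flagged as heuristic.

## Rod detection

Voxels above a density threshold are grouped into 26-connected components;
each sufficiently long (`min_length`, default 15 Å) and elongated
(`anisotropy_min`, default 2) component becomes a rod along its principal
axis. Two failure modes of naive thresholding are handled explicitly, both
consequences of ~7 Å maps with ~1.6 Å voxels:

* *fused tubes*: where two helices touch (contact points), components merge;
  clouds whose lateral RMS spread exceeds `split_residual` (3 Å — twice the
  single-tube value, well under half the tube spacing) are split by a
  deterministic 2-means on the lateral coordinates, provided the two halves
  are ≥ 5 Å apart laterally (a single thick tube never splits);
* *broken tubes*: at thresholds high enough to separate adjacent helices the
  tube is only 1–2 voxels thick and noise snaps it; nearly collinear
  fragments whose combined cloud is still rod-like (lateral RMS ≤ 2.5 Å)
  within a 4 Å gap are stitched back together.

For noisy maps a Gaussian pre-filter (`smooth_map()`, σ ≈ 0.8 Å at the
default voxel size) suppresses single-voxel noise before thresholding.

## The synthetic generator and what it emulates

`make_bundle()` generates ground-truth bundles of ideal helices; every
downstream stage is tested against it, so its geometry deserves scrutiny.
The defaults emulate a membrane subunit traced at medium resolution:

* a **single row** of membrane-inserted helices at 10 Å nearest-neighbour
  spacing — medium-resolution membrane subunits look like curved rows or
  sheets of helices, not symmetric rings;
* **unequal lengths** (default 26–36 residues) and **axial stagger**
  (midpoints uniform in ±8 Å of membrane depth);
* small random **tilts** (uniform 0–3°, cap 15°) and random rolls;
  alternating N→C direction;
* optionally (`surface_helix = TRUE`) the last helix lies near-horizontally
  along the membrane plane, packed against the side of the row one spacing
  away and off-centre along it — the arrangement of the archetypal
  proton-channel subunit, five inserted helices plus one along the membrane
  surface.

Several of these choices are *identifiability requirements*, not cosmetics.
A 15 Å satisfaction check is generous relative to a 10 Å-spaced bundle: any
two helices closer than ~17 Å can satisfy each other's contacts after
register/roll refinement, so in a symmetric ring or triangular packing many
helix permutations are geometrically equivalent and no search — by this or
any other method — could distinguish them. The row makes non-neighbour
placements violate clearly (≥ 2 spacings apart); the stagger breaks the
mirror through the membrane mid-plane (under which reversing every helix is
invisible); the off-centre horizontal helix breaks both the row-reversal and
the row-mirror symmetries by acting as a positional ruler: its contacts pin
each inserted helix to a position *along* the row. The real subunit this
emulates is asymmetric in exactly these ways.

`make_contacts()` draws true pairs (without replacement) from pairs with
Cα–Cα ≤ 8 Å and sequence separation ≥ 5, and false pairs from pairs > 20 Å
apart, with `round(n_pairs·(1−fp_rate))` true pairs — at the defaults,
85 true + 5 false of 90, so the generating model satisfies exactly 85/90 =
94.4% at 15 Å. Scores are distinct, rank-consistent placeholders: the
generator models no calibrated score distribution because coupling scores
from covariance pipelines have no portable error model. `render_map()` sums
an isotropic Gaussian per Cα with σ = resolution/(π√2) — any fixed monotone
resolution convention would do, since all tests compare relative density —
plus optional i.i.d. Gaussian noise. What the generator does *not* emulate:
CTF effects, non-white noise, reconstruction artefacts, B-factor falloff,
side-chain density, bent or kinked helices, and loops. Passing tests
demonstrate the machinery is correct under the stated geometry; they do not
certify performance on real micrograph-derived maps.

## Study conditions used by the tests

Problem sizes were chosen so each check measures what it claims while the
whole suite stays desk-scale:

* **Recovery** (the headline experiment): 100 seeded trials, six helices
  (five inserted + one surface), 90 contacts with 6% false positives,
  noise-free maps at 7 Å, rods detected at 0.6 of the map maximum,
  exhaustive search (46,080 assignments, ≈ 3 s each). Maps are noise-free
  here because the experiment isolates *assignment* recovery; detection
  robustness under noise is measured separately. With 5 false pairs free to
  be captured by any placement, occasional single-trial misses are expected;
  the recovery criterion is ≥ 95 of 100.
* **Detection under noise**: 50 seeded trials at noise σ = 10% of the map
  peak, smoothing σ = 0.8 Å, threshold 0.75 of the smoothed maximum;
  success requires all six rods matched one-to-one to the true axes.
* **State analysis**: rotations of 10°, 11°, 12°, 16° — recovered exactly
  from matched coordinates and within 1° through the map-alignment route;
  ring offsets modulo the 45° step of an 8-fold ring.
* **Averaging/heterogeneity**: 7 noisy copies (background noise shrinks by
  √7); 20-seed sign test that a rotating 8-fold ring raises voxel variance
  where it moves.

## Map operations

`align_maps()` maximises real-space normalised cross-correlation over a
coarse rotation-vector grid (default 10° steps within a 30° ball, i.e. a
*local* search — reconstructions of the same complex come pre-oriented;
widen `max_angle` for divergent inputs), with the best translation per
orientation from an FFT cross-correlation scan, then Nelder-Mead refinement
of all six parameters. Resampling is trilinear — adequate for ~7 Å features
and deterministic. Maps must share a voxel size; cross-pixel-size resampling
is out of scope. `average_maps()` reports the voxelwise mean and the
unbiased (N−1) variance; the variance map localises conformational
heterogeneity, which is exactly why averaging states blurs mobile regions.
`fsc()` computes shell-wise Fourier correlation; `fsc_resolution()` reports
both the 0.143 crossing and the value at a stated check frequency (default
1/10 Å⁻¹, the customary refinement-band check at this resolution) — both
numbers are returned, neither is chosen silently.

MRC files are written in the MRC2014 layout, mode 2 (32-bit float). Because
mode 2 stores float32, write→read is exact at float32 precision and is a
fixed point: a second round-trip is bit-identical. Modes 0/1/2 are read;
non-standard axis orders and anisotropic voxels are rejected by name.

## State comparison

`superpose()` is a proper-rotation least-squares (SVD) fit; reflections are
excluded and degenerate (collinear) point sets are an error rather than an
arbitrary answer. `rotation_angle_axis()` takes the angle from the rotation
trace and reports a *screw axis* — a direction plus a point in space,
because physically meaningful rotation axes of molecular sub-structures do
not pass through the origin; rotations under 0.1° have no well-defined axis
and are flagged instead of fabricated. `ring_offset()` reports the rotation
of one ring state relative to another modulo the symmetry step (45° for an
8-fold ring), computed from the circular mean of azimuthal differences,
which implicitly matches subunits by optimal circular shift; the fitted ring
axis has a deterministic sign convention (towards the dominant coordinate
axis). `interpolate_states()` is linear in Cartesian coordinates — a
visualisation device, not a trajectory; frames are flagged non-physical and
the chord-versus-arc shortening of rotating parts is quantified in the test
suite rather than hidden.

## Numerical choices and degenerate inputs

* Ties in the register/roll sweep and in solution ranking are always broken
  deterministically (distance comparisons carry a 1e-9 Å guard band so that
  compiled and interpreted routes agree).
* `fit_axis()` needs ≥ 3 residues and rejects coincident points; equivariance
  under rigid motions is tested numerically.
* `satisfaction()` errors when no pair is resolvable (the fraction would be
  undefined) rather than returning a default.
* All generators are bit-reproducible under `rng_seed`; every stochastic
  test fixes its seeds.

## Known limitations

* The exhaustive search scales as K!·2^K and is capped at K = 8; the greedy
  fallback carries no optimality guarantee.
* The register/roll sweep is a single pass; a pathological problem could
  favour a joint optimum the sweep misses, although the oracle-equivalence
  and recovery tests show no such case at the study conditions.
* Loops between helices are not modelled, and sequence connectivity between
  adjacent segments is not used as a constraint — only covariance pairs
  score an assignment.
* Detection thresholds are expressed relative to the map maximum; maps with
  strong density outliers would need a robust reference level instead.
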