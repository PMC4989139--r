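---
title: "Methods: dimer kinetics, interfaces and the lipid environment of a membrane GPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer kinetics, interfaces and the lipid environment of a membrane GPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dimerlens` analyses coarse-grain trajectories of two seven-transmembrane-helix
receptors in a POPC/cholesterol bilayer. This vignette documents the models
and conventions behind each stage, the tunable parameters, what the synthetic
generator does and does not emulate, and the design decisions taken where the
underlying methodology left genuine freedom.

## Geometry and units

Coordinates are in nm (the native GRO unit), times in ns, angles in degrees.
Boxes are orthorhombic; every inter-bead distance uses the per-component
minimum-image convention, which is exact for orthorhombic cells. Triclinic
boxes are rejected at parse time: the bilayer patches this package targets
are rectangular, and supporting triclinic minimum-image would complicate
every distance kernel for no practical gain.

## Dimer/monomer segmentation

The receptors' association state is read off the per-frame minimum distance
between their transmembrane beads. Loop beads are excluded: the third
intracellular loop extends far from the helical bundle and would dominate
close approaches that have nothing to do with interface formation.

Segmentation uses hysteresis with three thresholds:

| parameter | default | meaning |
|---|---|---|
| `dimer_cutoff` | 0.5 nm | a dimer interval opens below this |
| `monomer_threshold` | 1.0 nm | separations beyond this are unambiguous monomer |
| `dissociation_threshold` | 1.5 nm | an open interval closes above this |
| `min_dimer_frames` | 5 frames | consecutive sub-cutoff frames needed to open |
| `min_transient_duration` | 100 ns | dwell time separating transient dimers from grazing |

The 0.5/1.0/1.5 nm values are the standard criteria for coarse-grain
receptor association; the two dwell parameters resolve a genuine gap in that
methodology: distances between 0.5 and 1.5 nm are not assigned by the
printed criteria alone. Treating them as *continuations of the current
regime* (hysteresis) is the only assignment that makes both the dimer
criterion and the dissociation criterion simultaneously meaningful. Brief
sub-cutoff contacts are real in associating systems ("close approaches
before dimerization"), so an interval must both persist `min_dimer_frames`
to open and last `min_transient_duration` to count as a transient dimer;
shorter closed contacts are folded back into the monomer regime. A closed
interval's duration is `time[last frame] - time[first frame]`. An interval
that reaches the final frame unclosed is a stable dimer, and by construction
no further event can follow it. Dissociation events are exactly the closed
(transient) intervals.

## Rotational orientation

The relative rotation of the receptors in the dimer regime is described by
two angles. For receptor 1, θ₁ is the angle between the plane through its
backbone beads of residues 48 (helix I), 164 and 167 (helix IV) and the
plane through the 164–167 axis and bead 167 of receptor 2. Three beads of
one receptor plus one bead of the other define four points; we compute the
standard four-point dihedral 48–164–167–167′ (right-handed, IUPAC sign,
range (−180°, 180°]), which uses exactly the named beads and yields a single
signed angle. θ₂ is defined symmetrically. The inter-receptor leg is
min-imaged, so wrapped coordinates are safe. Degenerate (collinear) plane
definitions are flagged and the frame's angle reported missing.

A signed angle is the default output; a folded |θ| variant can be derived
trivially by the caller. Topology validation enforces that residue 48 lies
in helix I and residues 164/167 in helix IV, since the definition is
meaningless otherwise.

Orientation densities are 2-D histograms (`angle_bin_width`, default 10°)
normalized to unit mass. When compositions contribute unequal numbers of
dimerized simulations, each group is subsampled to the smallest count using
`config$seed`, so densities are comparable across membranes. Conformer
labels (A, A′, B, C) are axis-aligned rectangles in (θ₁, θ₂) space shipped
as an editable YAML file. The published regions exist only graphically, so
the defaults are a declared calibration on the packaged template geometry:
A is centred on the symmetric helix I–I homodimer (θ₁ ≈ θ₂ ≈ 0), A′ rings
it, B covers the site-2 (helix IV/V/VI) homointerfaces and C the
site-1 × site-2 heterointerfaces. Rectangles are left/bottom-closed,
right/top-open (closed at +180°), and overlaps are rejected at load time.

## Interface contact maps

A residue of receptor 1 contacts a residue of receptor 2 when any inter-bead
min-image distance is below `contact_cutoff` (0.5 nm); a helix pair is at
the interface when at least one residue contact joins it. Contacts involving
loops are tallied in a side table and excluded from the 7×7 maps, which is
what the helix-resolved figures in this literature plot.

The published normalization phrases ("by the time of occurrence and
simulation length"; "to the transient association period and the maximum
total number of transient association instances") are phrases, not
formulas. The implementation is declared as follows, and the raw
accumulators are always written alongside so alternative normalizations can
be applied post hoc:

* **Stable maps** — per event, the fraction of event frames each pair is at
  the interface, weighted by event duration / simulation length, summed
  over events, then divided by the matrix maximum (top pair = 1).
* **Transient maps** — per event, the per-pair fraction of event frames at
  the interface (occurrence normalized to the association period), summed
  over events, divided by the maximum per-pair instance count. Three
  equal-length events on one pair versus one event on another yields the
  3:1 ratio this normalization implies.

Maps are computed ordered (receptor 1 × receptor 2) and also reported
symmetrized (unordered pairs, off-diagonals folded together), since the
figures being emulated do not disambiguate receptor order. Normalization is
per composition; whether the published color scales were global across
membranes is unstated (one caption notes a different scale for the pure
POPC panel), so per-composition is implemented.

## Lipid occupancy

Maximum occupancy of a residue is the longest time a *single* lipid
molecule remains continuously within `lipid_contact_cutoff` of the residue,
normalized by the regime length. The precise contact definition is deferred
to earlier work in the source methodology, so it is a package default:
0.6 nm, any-bead-to-any-bead, zero gap tolerance (a single frame outside
the cut-off breaks a run) — all configurable and recorded in output
metadata. Runs are counted on the concatenated regime-frame sequence:
regime interruptions (e.g. a dimer excursion inside the monomer regime) do
not break a run, which is required for the limit case "resident throughout
the regime → occupancy exactly 1" to hold when a regime comprises several
intervals. Profiles are averaged over the two receptors (each monomer is an
independent observation) and can be normalized to their maximum for
figure-style output.

## Bilayer thickness maps

Thickness is the mean upper-leaflet minus mean lower-leaflet phosphate *z*
per cell of a `grid_bin` (0.2 nm) grid. Frames are transformed into the
receptor body frame — origin at the transmembrane centroid, +x toward the
helix-I centroid — so helix sectors are fixed directions in the map.
Leaflets are assigned per frame by the sign of *z* relative to the
phosphate median: robust, cheap, and exact for intact bilayers (the
generator never flips a phosphate across the midplane). The map is
normalized by the mean thickness of far-field cells (farther than
`farfield_min_distance` = 3 nm from any receptor bead), making the
far-field mean exactly 1 by construction; >1 is local thickening (positive
hydrophobic mismatch), <1 local thinning. Cells with no samples in either
leaflet are reported missing rather than interpolated.

## Interface occupancy score

Per-helix occupancy is the maximum residue occupancy over the helix's
residue range, normalized by the best helix. The "probability of a dimer
conformation" is not given an estimator in the source methodology; it is
implemented as the per-helix marginal of the stable contact map (unordered
populations summed over partners, rescaled to a maximum of 1). The score
matrix entry (h_occ, h_int) is normalized occupancy × interface
probability. Both noise filters — occupancy ≥ 0.7 and interface probability
≥ 0.7 — are applied *after* the product, to entries (whether the published
filters preceded or followed the product is unstated; applying them to the
finished entries is the more conservative choice and is documented in the
output metadata). Diagonal entries read as lipid occupancy on interface
helices, off-diagonals as occupancy away from the interface.

## The synthetic generator

The generator is kinematic — rigid placement plus random walks — not a
physics simulator. Molecular dynamics is deliberately out of scope; exact
ground-truth control is the design goal, because it is what makes every
analysis stage falsifiable.

What it emulates:

* two rigid seven-cluster receptors (five backbone beads per helix on a
  1.3 nm ring, one sidechain bead, two intracellular loop beads) diffusing
  in-plane at 0.001 nm²/ns — a realistic coarse-grain receptor mobility —
  with periodic wrap;
* planted dimer intervals: the requested interface pair is placed in
  contact at 0.42 nm with every other helix pair clear of the 0.5 nm
  cut-off, at the requested (θ₁, θ₂). Because the angles are a function of
  the relative placement, the generator solves for in-plane rotations
  (constrained to ±18° about the face-to-face geometry) that realize them
  exactly; requests incompatible with the requested interface raise a
  generation error before any frame is written. `NA` angles request the
  natural facing geometry. Transient intervals exit beyond 1.5 nm in one
  frame;
* grazing approaches (0.6–0.9 nm, shorter than `min_dimer_frames`) and
  sub-dwell folded contacts, so the segmentation hysteresis is genuinely
  exercised;
* lipid hot-spots: one dedicated lipid per hot-spot is held 0.35 nm from
  its residue for a contiguous run of regime frames of length
  `round(target × regime length)`; all other lipids are actively kept
  1 nm away from hot-spot residues so the planted occupancy is exact to
  one frame fraction;
* a sectored thickness field: phosphate *z* follows
  `±(t₀/2) · m(x, y)` with per-(receptor, helix-sector) multipliers inside
  2.5 nm, a linear taper to 1 at 3 nm, and an exactly flat far field;
  deviations from the two receptors add. During the monomer regime the
  walk keeps receptor centres ≥ 6.05 nm apart so the two deformation
  neighbourhoods cannot overlap and each receptor's sectors are recovered
  cleanly.

What it does not emulate: force fields, thermostats, membrane undulations,
realistic association kinetics (entry into a dimer interval is a placement,
not a diffusive encounter), lipid packing, or receptor flexibility.
Passing recovery tests therefore demonstrates the *analysis* is correct,
not that it is robust to every pathology of real trajectories — though the
grazing, noise and multi-event scenarios cover the failure modes the
method's thresholds exist to handle.

The four packaged scenarios (one per composition: 0, 9, 30, 50 mol%
cholesterol) use 1500 frames at 15 ns spacing (22.5 µs) in a
12 × 12 × 10 nm box with 220 lipids — sizes chosen so the full pipeline
runs in well under five minutes per scenario on one CPU while every planted
feature remains statistically unambiguous. Their event counts follow the
qualitative published picture: helix I–I dominates the stable interface in
pure POPC and disappears at high cholesterol, dissociation events increase
with cholesterol, cholesterol hot-spots sit on helices IV–VI and on the
interface helix in the dimer regime. Scenario seeds are part of the study
conditions: each scenario regenerates bit-identically.

## Numerical choices

* Dimer placement solving: Nelder–Mead over the two in-plane rotations with
  the separation solved by bisection (`uniroot`, tol 1e-10) at each step;
  achieved angles must match requests within 0.5° or generation fails.
* Distance kernels are vectorized outer-product computations; the
  minimum-distance path is verified against an exhaustive double-loop
  oracle to 1e-9 nm.
* Matrix TSV output uses `%.17g`, so written values round-trip bit-exactly;
  `NaN` is written as `NA`.
* The GRO writer emits three-decimal coordinates (format precision);
  round-trips are exact at that precision.
* Degenerate inputs: empty dimer regimes yield empty (warned) densities and
  maps rather than errors; zero lipids of a requested kind yield an all-zero
  profile with a warning; an empty leaflet is an error.

## Limitations

* XTC (binary) trajectories are not read; GRO is the interchange format,
  and converting XTC → GRO externally (e.g. `gmx trjconv`) is documented as
  the supported path.
* Orientation angles assume both receptors stay roughly upright (no tilt
  model); the generator never tilts receptors.
* The conformer rectangles are calibrated to the packaged template
  geometry; real systems should recalibrate them against their own
  orientation densities.
* Occupancy is not split per leaflet, and no order-parameter or curvature
  analysis is attempted.
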