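# dimerlens

Analysis of coarse-grain molecular-dynamics trajectories of two
membrane-embedded G protein–coupled receptors (GPCRs) in a POPC/cholesterol
bilayer. The package is aimed at people studying receptor dimerization in
membranes — it turns raw bead trajectories into the quantities such studies
report: when the two receptors are a dimer, which transmembrane helices form
the interface, how the receptors are rotated against each other, where
lipids reside on the receptor surface, and how the bilayer deforms around
the protein.

## What it computes

For a trajectory of two seven-transmembrane-helix receptors (helices I–VII,
residues numbered per UniProt P08908) with POPC (phosphate bead `PO4`) and
cholesterol:

* **Dimer/monomer segmentation.** The per-frame minimum inter-receptor
  distance *d(t)* over transmembrane beads (minimum-image convention,
  orthorhombic box) is segmented with hysteresis: a dimer interval opens at
  the first of ≥ 5 consecutive frames with *d* < 0.5 nm and closes when
  *d* > 1.5 nm (a dissociation event). Intervals reaching the final frame
  are **stable** dimers; closed intervals lasting ≥ 100 ns are **transient**
  dimers; shorter contacts are grazing approaches and stay monomer.
* **Rotational orientation.** θ₁ is the signed four-point dihedral over the
  backbone beads 48–164–167 of receptor 1 and 167 of receptor 2 (θ₂
  symmetrically), mapped to (−180°, 180°]; 2-D orientation densities and
  conformer labels (A, A′, B, C) follow.
* **Helix–helix contact maps.** Residue contacts at 0.5 nm define the
  interface helix pairs; 7×7 maps are accumulated separately for stable
  dimers (event-duration / simulation-length weighting) and transient
  dimers (normalized to the association period and the maximum instance
  count).
* **Lipid occupancy.** Per residue, the longest single-molecule residence
  run within 0.6 nm, normalized to the regime length — the *maximum
  occupancy* of cholesterol or POPC in the monomer or dimer regime.
* **Bilayer thickness.** Receptor-centred, body-frame maps of
  phosphate-to-phosphate distance, normalized to the far-field bilayer
  (>1 = local thickening, positive hydrophobic mismatch).
* **Interface occupancy score.** Per helix pair, normalized occupancy ×
  interface probability, with both 0.7 noise filters; diagonal dominance
  indicates lipids residing on the helices that form the interface.

Because public trajectory data for such systems is scarce, the package
ships a **synthetic trajectory generator** with planted ground truth —
dimer intervals with chosen interface helices and orientation angles,
grazing approaches, lipid hot-spots with exact target occupancies, and
sectored bilayer-thickness deformations — so every analysis stage has a
recovery test. Four packaged scenarios mirror the 0/9/30/50 mol%
cholesterol study design.

## Worked example

```r
library(dimerlens)

sc  <- reference_scenarios()[[2]]        # 9% cholesterol scenario
run <- generate_trajectory(sc)
seg <- segment_regimes(distance_series(run$trajectory, run$topology))
seg$dimer_events
#>   interval start  end     class
#> 1        2   150  250 transient
#> 2        4   400  500 transient
#> 3        6   650  750 transient
#> 4        8   870  970 transient
#> 5       10  1100 1500    stable
```

Five dimer events: four dissociations (transient dimers) and one stable
dimer persisting to the end of the 22.5 µs trajectory. The stable interface
is helix IV–IV:

```r
runs <- list(list(trajectory = run$trajectory, topology = run$topology,
                  segmentation = seg))
stable_contact_map(runs)
#> stable helix contact map (9% cholesterol, 1 event(s))
#>     I II III IV V VI VII
#> IV  0  0   0  1 0  0   0     (all other cells 0)
```

Cholesterol occupancy in the dimer regime peaks on helix IV (a planted
hot-spot on residue 160 at 0.9 occupancy), and the interface occupancy
score couples it to the IV–IV interface:

```r
occ <- residue_occupancy(run$trajectory, run$topology,
                         regime_frames(seg, "dimer"), "CHOL", regime = "dimer")
round(helix_occupancy(occ, run$topology), 3)
#>     I    II   III    IV     V    VI   VII
#> 0.007 0.006 0.003 1.000 0.000 0.000 0.005

interface_occupancy_matrix(helix_occupancy(occ, run$topology),
                           interface_probabilities(stable_contact_map(runs)),
                           composition = 9)
#> Interface occupancy score (CHOL, 9% cholesterol):
#>     IV column, IV row = 1; every other entry filtered to 0
```

The score matrix has its mass on the diagonal (IV, IV): cholesterol sits on
the helix that forms the dimer interface.

The whole chain — kinetics, orientation, contacts, environment, score, plus
a reproducibility manifest with md5 sums — runs as one call:

```r
run_pipeline(list(scenario = "chol_09"), "out/chol_09")
```

A thin command-line wrapper lives at `inst/scripts/dimerlens.R`
(`generate`, `run-all`, `print-config` subcommands).

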