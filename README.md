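# SynapseQuant

Quantification of bead-activated B-cell immune synapses from
multi-channel 3D fluorescence z-stacks.

When a B cell engages an antigen-coated bead it forms an immune synapse:
the centrosome and LAMP1+ endolysosomes reposition toward the bead, the
cell spreads, B-cell receptors cluster centrally, and bead-bound antigen
is extracted into intracellular compartments. SynapseQuant implements the
image-quantification side of this biology as a tested, reusable R
package: every per-cell metric is an exported function over explicit S4
containers (`ChannelStack`, `Scene`, `BinaryStack`, `VoxelModel`,
`LabeledComponents`), and a synthetic-scene generator with analytic
ground truth makes the whole chain verifiable without microscopy data.

## Metrics

* **Polarity index** — the label's fluorescence centre of mass **L** is
  projected onto the axis from the cell centre of mass **C** to the bead
  centre of mass **B**; the index is the signed projection length over
  the axis length,

  `PI = ((L − C) · (B − C)) / |B − C|²`,

  ranging −1 (anti-polarized) through 0 (unpolarized) to +1 (label at
  the bead). Computed for any channel (`scenePolarity`,
  `polarityIndex`).
* **Around-bead fraction** — channel intensity within a concentric disc
  (default radius 3.5 µm) around the bead over total cell intensity
  (`aroundBeadFraction`).
* **Antigen extraction** — bead-area antigen fluorescence on sum
  projections over a time course, normalized to 100 % at time 0
  (`extractionRemaining`).
* **Spreading area, circularity, recruitment index** at the synaptic
  plane — shoelace/pixel-count areas, `4πA/P²` circularity with a
  smoothed contour perimeter, and the central-vs-total fluorescence
  density ratio (central region = outline scaled to ¼ area) minus one
  (`spreadingArea`, `circularity`, `recruitmentIndex`).
* **3D volumetry** — threshold → per-slice erosion → z-linked 3D
  components (8-connected in-plane, face-adjacent across slices) with
  volumes by voxel counting (`thresholdStack`, `erodeSlices`,
  `linkRoi3d`), particle counting in a physical area window
  (`filterParticles2D`, `countFoci`), volume binning (`binVolumes`).
* **Colocalization and compartment selection** — voxel-model
  intersections, all-or-nothing selection of compartments containing a
  marker, nested containment percentages (e.g. LAMP1+Ag+ of LAMP1+, and
  LAMP1+Ag+SNX5+ of LAMP1+SNX5+), Pearson correlation over the cell
  z-stack and Manders M1 over a reference label (`intersect`,
  `selectCompartmentsContaining`, `nestedFraction`, `pearsonColoc`,
  `mandersM1`).

`runPipeline()` drives everything from a validated YAML config and emits
one metric record per cell; `summarizeMetrics()` adds per-group
mean/SEM/n tables. A thin CLI (`inst/scripts/synapsequant.R`) exposes
`generate` / `quantify` / `summarize` verbs.

## Worked example

```r
library(SynapseQuant)

spec <- sceneSpec(nCompartments = 40L, polarization = 0.75, seed = 42L)
sc <- generateScene(spec)
sc
#> Scene: 3 channel(s) [LAMP1, Ag, SNX5], 27 x 68 x 88 [z,y,x]
#>   voxel 0.35 x 0.15 x 0.15 um, 1 bead(s), cell mask, ground truth

scenePolarity(sc, "LAMP1")
#> PolarityIndex 'LAMP1': 0.3069
expectedPolarity(spec, nSim = 200)$mean   # placement-simulation oracle
#> [1] 0.319

bin   <- erodeSlices(thresholdStack(getChannel(sc, "LAMP1"), "otsu"))
comps <- linkRoi3d(bin)
countComponents(comps); volume(comps)
#> [1] 14          # LAMP1+ compartments
#> [1] 7.4         # total volume, um^3

agM  <- asVoxelModel(erodeSlices(thresholdStack(getChannel(sc, "Ag"), "otsu")), "Ag")
snxM <- asVoxelModel(erodeSlices(thresholdStack(getChannel(sc, "SNX5"), "otsu")), "SNX5")
nestedFraction(comps, agM, snxM)[c("primaryPercent", "nestedPercent")]
#> $primaryPercent 96.3   # % of LAMP1+ volume containing antigen
#> $nestedPercent  92.2   # % of LAMP1+SNX5+ volume also containing antigen
```

The measured polarity index (0.31) agrees with the placement oracle
(0.32) for this cohort's polarization of 0.75: the generator displaces
compartments toward the bead with probability `p`, so the index grows
monotonically with `p` rather than reaching +1 (which would require all
label mass at the bead centre). The containment percentages are high
here because the generator assigns markers independently per compartment
with probability 0.5, so most compartments carry some antigen overlap.

## Documentation

The methods vignette (`vignettes/synapse-quantification.Rmd`) describes
the measurement model, the synthetic-scene generator and its defaults,
numerical conventions (axis order, anisotropy, boundary rules,
perimeter estimation) and known limitations.
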