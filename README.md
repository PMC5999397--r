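# iceProfiler

Quantitative characterization of single-particle cryoEM grids from
screening cryo-electron tomograms.

Tomography of grid holes shows that the vast majority of particles on
typical preparations are adsorbed to one of the two air-water interfaces
(AWIs) bounding the vitreous ice film — in layers 5–10 nm from the
surface, frequently with preferred orientations — and that the interfaces
are usually tilted a few degrees from the beam normal and curved across
the hole. These geometric facts control collection quality: the layer
separation *t* and the layer tilt α set defocus-error resolution budgets,
ice thickness sets signal, and the annulus where only one layer fits is
the best place to put the beam.

iceProfiler is for microscopists and software folk who want those numbers
from a tomogram, plus a fully synthetic test bed. It provides:

* **Geometry** — locate both AWIs (density gradient, surface
  contamination, or a particle layer plus its known offset), measure the
  ice thickness map, interface tilt and the C1–C4 curvature class
  (`locateInterfaces`, `thicknessStats`).
* **Particles** — Laplacian-of-Gaussian blob detection, signed
  interface distances, layer assignment at a 10 nm adsorption cutoff,
  adsorbed fraction, layer tilt, saturation against the hexagonal
  packing limit 0.9069, projection overlap, and B1–B5 behavior codes
  (`detectParticles`, `assignToLayers`, `projectionOverlap`).
* **Orientation** — mean resultant length R with mode clustering on the
  sphere, and the projection-coverage gain from collecting at stage
  tilts (`orientationDispersion`, `tiltExpandedCoverage`).
* **CTF calculators** — relativistic wavelength, the 90°-out-of-phase
  defocus-error limit d = √(2λ·δz), tilted-field and bilayer defocus
  offsets, duplicate-defocus rescue pairs, cosine dose schemes
  (`defocusErrorResolutionLimit`, `tiltDefocusOffset`, `tiltDoseSeries`).
* **Survey** — a packaged 46-sample grid survey with thickness/tilt
  aggregation under propagated measurement error
  (δq = √(Σδx²)/N, combined with the SD in quadrature) and the
  ideal/near-ideal classification (`loadSurvey`, `groupIceStats`,
  `classifyConditions`).
* **Advisor** — a rule cascade turning a measured characterization into
  collect-at-offset / tilted-collection / collect-with-caveats / reject
  (`recommendStrategy`).
* **Phantoms** — a synthetic grid-hole tomogram generator with exact
  ground truth: quadratic interface profiles with plane tilt, adsorbed
  layers and free particles, contamination, debris, noise and a
  missing-wedge filter (`makePhantom`), written/read as MRC2014
  (`writeMRC`, `readMRC`).

## Worked example

Simulate a typical hole (90 % adsorption, 5 nm layers, concave
30 nm-centre / 100 nm-edge ice, 4° interface tilt) and profile it:

```r
library(iceProfiler)

ph  <- makePhantom(phantomConfig(seed = 7L))
rep <- runPipeline(ph$volume, particleDiameter = 10, holeRadius = 100)
rep
#> ProfileReport
#>   volume: 144x144x96 voxels at 16 A
#> IceGeometry: t_center_min 30.8 nm, t_edge_min 70.6 nm (+/- 5 nm)
#>   curvature C3/C3 (bottom/top), tilt 3.8/4.1 deg
#>   197 particles in 2 layer(s); adsorbed fraction 0.929
```

The measured 30.8 nm centre thickness, C3/C3 curvature and ~4° tilt
recover the configured phantom within the 5 nm / 1° measurement errors,
and the 0.929 adsorbed fraction recovers the configured 90 % (free
particles wandering within the 10 nm cutoff account for the excess).
`writeProfileReport(rep, "report.json")` serializes everything with units
in the field names.

CTF budget for a tilted field of view:

```r
dz <- tiltDefocusOffset(4096, 10)   # 4096 A field, 10 deg tilt -> 361 A
defocusErrorResolutionLimit(dz, kv = 300)
#> [1] 3.770759    # ~4 A: the worst-corrected particles are capped there
```

Survey statistics from the packaged tables:

```r
rec <- loadSurvey()
groupIceStats(rec, "gold_spotiton", "center")[c("n", "mean", "sd")]
#> $n [1] 11   $mean [1] 30   $sd [1] 12.61312
```

A thin CLI over the same functions ships in
`inst/scripts/iceprofiler.R` (subcommands `simulate`, `profile`,
`ctf-limit`, `survey`, `advise`).

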