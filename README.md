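# flytomo

Time-stepped reconstruction of continuous-rotation (fly-scan) parallel-beam
tomography, with a built-in synthetic testbed for time-resolved imaging of
enamel demineralization.

## The problem

Classical micro-CT treats a tomographic scan as an indivisible unit: rotate
180°, reconstruct, repeat. When the sample is *changing* during the
experiment — e.g. a block of dental enamel dissolving in citric acid — the
time resolution of the resulting 4D series is limited by the duration of a
full scan plus its turnaround.

A fly-scan acquisition instead rotates the stage continuously from 0° to an
integer multiple of 360° while the detector records frames at a fixed
period. Projection index *i* then maps linearly onto both rotation angle and
wall-clock time:

    θ_i = θ_0 + i·Δθ        t_i = i·(t_exp + t_overhead)

Any contiguous block of frames spanning ≥ 180° is a valid tomogram. With the
fence-post convention, a 180° window at Δθ = 0.072° holds
180/0.072 + 1 = **2501** projections, a 0–1080° scan file holds **15 001**,
and the file partitions into **six** disjoint 2501-frame tomograms at stride
2500. Because windows may *overlap*, the nominal time step between
successive reconstructions is no longer one scan duration but one stride —
down to a single frame period (0.5 s here). `flytomo` implements this
time-stepping interpretation end to end:

| module | what it does |
|---|---|
| `ScanGeometry` | exact index ↔ angle ↔ time bookkeeping of the fly scan |
| `PhantomState` | time-evolving attenuation phantom: enamel disc with rod/inter-rod texture and a growing acid-dissolution cavity |
| `simulateFlyscan` | forward-projects the evolving phantom frame by frame; dark/flat fields, Poisson + read noise |
| `flatDarkCorrect`, `negLog`, `assembleSinogram` | raw frames → Beer–Lambert line-integral sinograms |
| `enumerateWindows`, `extractWindow` | overlapping 180° window enumeration with per-window angle/time labels |
| `fbpReconstruct`, `reconstructWindow` | filtered back-projection at arbitrary (wrapped) start angles |
| `differenceMap`, `segmentCavity`, `progressionCurve` | grey-value change maps, cavity segmentation, volume-vs-time curves |
| `runDemo` | one-shot synthetic experiment at desk scale |

## Worked example

The reference acquisition and its six-window layout:

```r
library(flytomo)
geom <- referenceGeometry()   # 15 001 frames, 0.072°, 0.5 s, 10x / 0.325 um
nProjectionsForRange(geom, 180)   # 2501
angleOfIndex(geom, 15000)         # 1080
voxelSizeFor(geom, 4)             # 0.8125 (um at the 4x objective)
windowTable(enumerateWindows(geom, 2501L, 2500L))
#>   label start_index n_window start_angle_deg mid_angle_deg t_start_s t_mid_s t_end_s dt_from_first
#> 1     1           0     2501               0            90         0     625    1250      00:00:00
#> 2     2        2500     2501             180           270      1250    1875    2500      00:20:50
#> 3     3        5000     2501             360           450      2500    3125    3750      00:41:40
#> 4     4        7500     2501             540           630      3750    4375    5000      01:02:30
#> 5     5       10000     2501             720           810      5000    5625    6250      01:23:20
#> 6     6       12500     2501             900           990      6250    6875    7500      01:44:10
```

The full synthetic experiment — simulate a 0–1080° fly scan of the
dissolving phantom, reconstruct the six disjoint windows, and quantify the
cavity:

```r
res <- runDemo(demoConfig(seed = 17L), out_dir = "flytomo-demo")
as.data.frame(res$curve)
#>   time_s volume mean_grey
#> 1    150      0   0.01177
#> 2    450     90   0.01168
#> 3    750    185   0.01151
#> 4   1050    274   0.01136
#> 5   1350    345   0.01123
#> 6   1650    406   0.01113
```

`volume` is the segmented demineralized area (µm², one slice) against the
window mid-times; the phantom's ground-truth areas at those times are
0, 56, 158, 248, 322, 386 µm² (the segmentation over-counts slightly at the
blurred cavity rim; the final area is within ~5 %). `mean_grey` is the mean
reconstructed attenuation inside the reconstruction circle, which falls
monotonically as mineral dissolves. The output directory also contains the
scan container (`scan/`, multi-page 32-bit TIFF + JSON sidecar), one
`tomo_NNN.tif` per window, `windows.csv`, `curve.csv/png`, a structured
`run.log` and a `summary.json` of built-in consistency checks, all stamped
with the configuration hash.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "flytomo.R", package = "flytomo")` with subcommands
`demo`, `simulate`, `windows`, `recon` and `analyze`.

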