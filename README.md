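# lamellakit

Curation and quality analysis of subtomogram-averaging particle sets from
cryo-FIB-milled lamellae.

When a cell is thinned into a lamella by focused-ion-beam milling and imaged
by cryo-electron tomography, two properties of the slab decide how far
subtomogram averaging can go: the **local lamella thickness** (the slab is
wedge-shaped, thicker toward the back, and thick ice costs signal) and the
**ion-damage layer** (implanted gallium and collision cascades degrade a
zone under each milled surface). `lamellakit` measures both directly from
template-matching results and turns them into reproducible particle
selections:

* **Geometry / straightening** — per tomogram, fit a reference plane
  `z = a·x + b·y + c` through the raw template-match coordinates, flatten
  `z`, read the two lamella surfaces off the flattened-`z` histogram (edges
  where the match count drops below half the plateau), and derive each
  particle's depth to the closest surface and the tomogram's local
  thickness, all in nm.
* **Curation** — equal-count thickness groups, fixed-size depth bins at 5-nm
  centres, the high-quality filter (thickness < 180 nm **and** depth
  > 30 nm, strict), nested random subsets with a Kolmogorov–Smirnov
  thickness-bias check, and whole-tomogram random selections.
* **Resolution** — Fourier shell correlation between half-maps,
  `FSC(s) = Re Σ F_a F_b* / √(Σ|F_a|² Σ|F_b|²)` per one-voxel shell, with
  interpolated threshold crossings (0.143 / 0.5), and Rosenthal–Henderson
  fits `1/d² = (2/B)·ln N + c` giving the B-factor `B = 2/slope` (Å²) with
  Nyquist-pinned points excluded.
* **Damage** — per-tomogram CC/CCmax normalisation and an explicit
  hinge-regression estimate of the damage-layer depth
  (`cc(d) = c_surf + (c_plat − c_surf)·min(d, d_break)/d_break`, breakpoint
  grid-scanned at 1 nm, percentile-bootstrap CI).
* **Acquisition** — dose-symmetric tilt schemes with pretilt and grouping,
  cumulative dose, and critical-exposure dose weights
  `exp(−dose / (2·(a·f^b + c)))`.
* **Synthetic data** — a wedge-lamella particle simulator with ground truth,
  damage-modulated CC scores, and half-map pairs with prescribed spectral
  SNR, so every stage is testable without tomograms.

I/O: minimal readers/writers for RELION-dialect particle STAR files
(unknown columns preserved), MRC mode-2 volumes, per-tomogram metadata
tables, and rawtlt-style angle files.

## Worked example

The bundled demonstration simulates a 12-tomogram wedge lamella (local
thickness running ~43–255 nm front to back, ~800 template matches per
tomogram, a 30-nm ramp damage layer), straightens it, and runs the three
analyses:

```r
library(lamellakit)
demo <- run_demo(seed = 1)
print(demo)
#> Synthetic lamella demonstration (seed 1)
#>
#> Straightened 9035 particles across 12 tomogram(s)
#>   local thickness 50-245 nm; 171 particle(s) outside slab
#>
#> Thickness analysis: 3 equal-count groups
#>   group    n key_min key_max
#> 1     1 3012      50     160
#> 2     2 3012     160     210
#> 3     3 3011     210     245
#>   group 1: B = 341 A^2
#>   group 2: B = 279 A^2
#>   group 3: B = 268 A^2
#>
#> Depth analysis: 3425 particles in the thickness window
#> Damage-layer depth: 30 nm (bootstrap 95% CI 29-31 nm, 100 resamples)
#>   CC/CCmax: 0.580 at surface -> plateau 0.864; residual RMS 0.0518, n = 3425
#>
#> High-quality vs random comparison:
#>               set    n mean_depth_nm mean_thickness_nm mean_cc_norm
#>      high_quality 2225      50.48636          141.4427    0.8636713
#>  random_particles 2225      44.01685          172.8270    0.8043229
#>  random_tomograms 2225      38.50062          157.2360    0.8012475
```

Reading the output: the straightening recovers the simulated wedge (local
thickness 50–245 nm, estimated at 5-nm histogram resolution against a true
43–255 nm span) and flags the few particles placed outside the estimated
surfaces. The thickness analysis splits the particles into equal tertiles
and fits a Rosenthal–Henderson B-factor per tertile from simulated half-map
resolutions. The depth analysis restricts to the 140–190 nm thickness
window and recovers the generator's 30-nm damage layer exactly, with the
CC/CCmax profile rising from 0.58 at the surface to a 0.86 plateau. The
quality comparison shows the high-quality selection (thin lamellae, outside
the damage zone) has markedly higher mean CC/CCmax than size-matched random
selections.

Individual steps are ordinary functions returning classed objects with
`print`/`coef`/`predict`/`plot` methods, e.g.

```r
st  <- straighten(read_particle_star("particles.star"),
                  read_tomogram_meta("tomos.tsv"))
hq  <- select_high_quality(st$particles)          # <180 nm, >30 nm
fsc <- compute_fsc(read_mrc("half1.mrc"), read_mrc("half2.mrc"))
resolution_at(fsc, 0.143)
```

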