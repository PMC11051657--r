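---
title: "Lamella geometry, ion damage, and particle quality: methods"
author: "lamellakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lamella geometry, ion damage, and particle quality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellakit)
```

# The problem

Cells that are too thick for transmission imaging are thinned into lamellae
by cryo-focused-ion-beam (FIB) milling before cryo-electron tomography.
Two properties of the resulting slab limit what subtomogram averaging (STA)
can recover from it:

* **local lamella thickness** — the slab gets thicker from the front to the
  back of the lamella (the milling beam geometry produces a wedge), and
  thicker ice means weaker signal per tilt image;
* **the ion-damage layer** — implanted gallium ions and their collision
  cascades degrade a zone under each milled surface, so particles close to a
  surface are of lower quality than particles deep inside the slab.

`lamellakit` quantifies both effects on template-matched particle sets and
turns them into selection rules: per-particle *depth* (distance to the
closest lamella surface, nm) and per-tomogram *local thickness* (nm), plus
the stratification, resolution and damage analyses built on them.

# In-silico straightening

Reconstructed tomograms are not aligned with the slab: the lamella carries a
pretilt (about +8 degrees here), a loading offset, and some inherent
non-flatness. Per tomogram, the straightening therefore:

1. fits the reference plane $z = a x + b y + c$ through **all** raw
   template-match coordinates by ordinary least squares
   (`fit_reference_plane()`). Raw matches are used deliberately: false
   positives are distributed through the slab volume and do not bias a plane,
   while classification could deplete specific regions. No outlier rejection
   is applied by default; a Tukey-bisquare reweighted variant is available
   via `robust = TRUE` for pathological tomograms.
2. subtracts the plane from every particle's $z$ (`flatten_z()`), leaving the
   slab flat and centred near $z = 0$;
3. histograms the flattened $z$ (converted to nm through the tomogram pixel
   size) and places each surface where the match density *drops off sharply*
   (`estimate_surfaces()`). Operationally: the plateau level is the median
   count over the occupied interior bins, and each edge is the outer
   boundary of the outermost bin whose count still reaches
   `dropoff_fraction` of the plateau. Taking the outermost qualifying bin
   (rather than stopping at the first failing one) makes the rule robust to
   single noisy interior bins, while a stray outlier beyond the slab cannot
   extend the edge because an isolated bin essentially never reaches half
   the plateau count.
4. computes each particle's depth as the distance to the *closest* surface
   (`particle_depth()`), with no distinction between top and bottom.
   Particles falling outside the estimated slab are kept with negative depth
   and an `outside_slab` flag, so surface-estimation error remains visible
   downstream.

**Parameters.** `bin_width_nm = 5` matches the 5-nm granularity of the depth
analysis and is roughly one ribosome diameter — finer bins are shot-noise
limited at realistic match densities (a few hundred matches per tomogram),
coarser bins blur the edge. `dropoff_fraction = 0.5` reads "drops off
sharply" as the half-plateau point; for a uniform slab the expectation of the
edge bin is exactly half the plateau, so the rule is unbiased there.
`min_support = 100` refuses tomograms where the histogram would be mostly
empty bins. All three are exposed because they are operational choices, not
measurements. The canonical internal unit is nm; STAR coordinates stay in
voxels and are converted through the per-tomogram pixel size (Angstrom per
voxel, e.g. 4.9 for a binned reconstruction).

The plane fit is per tomogram, not per lamella: local thickness and local
non-flatness vary along a lamella, and each tomogram samples a small enough
patch for a single plane.

# Curation rules

* `split_equal_count()` builds thickness groups by equalising particle
  counts: groups are contiguous blocks in stably sorted key order, sizes
  differ by at most one, extras go to the lowest-key groups. Tie handling at
  boundaries is therefore deterministic (input order), which matters only
  when many particles share one measured thickness.
* `select_depth_bins()` picks, for each depth centre (default 5–50 nm in
  5-nm steps), the `per_center_n` particles nearest that depth. Groups may
  overlap when the surface region is underpopulated; the consecutive-centre
  overlap fraction is reported rather than hidden.
* `select_high_quality()` applies **strict** inequalities — thickness
  < 180 nm and depth > 30 nm — mirroring "smaller than" / "closer than …
  excluded" semantics; records exactly at a threshold are dropped.
* `random_subsets()` draws *nested* subsets (sequential reduction, one
  permutation), so a 250-particle set is contained in the 500-particle set,
  and verifies each subset's thickness distribution against the full table
  with a two-sample Kolmogorov–Smirnov test (warning below `p = 0.01`). The
  KS test is a concrete reading of "checked to ensure unbiased thickness
  distribution"; the threshold is configurable.
* `select_by_tomogram()` adds whole tomograms in random order until the
  particle target is reached, then trims the last tomogram — the
  comparison-set construction that favours multiparticle refinement.

# FSC and Rosenthal–Henderson fitting

`compute_fsc()` implements the plain correlation
$\mathrm{FSC}(s) = \mathrm{Re}\sum F_a F_b^{*} \big/
\sqrt{\sum |F_a|^2 \sum |F_b|^2}$
over shells one Fourier voxel wide, frequency assigned at the shell centre,
after optional voxelwise masking. No mask-correction (phase randomisation)
or weighting is applied: the module targets synthetic validation and
comparative curves, not map deposition. `resolution_at()` interpolates the
first downward crossing of the threshold linearly between the bracketing
shells (default threshold 0.143; 0.5 available) and returns the Nyquist
resolution with a `no_crossing` flag when the curve never crosses.

`rosenthal_henderson_fit()` fits $1/d^2 = (2/B)\ln N + \text{intercept}$ by
least squares and reports $B = 2/\text{slope}$ (Å²). Points whose resolution
sits within one shell (operationally, 5%) of Nyquist carry no slope
information — the resolution is clipped, not measured — and are excluded
from the default fit range; when fewer than two informative points remain,
or the slope is non-positive (as happens for multiparticle-refined series
with no linear regime), the function refuses with a clear error rather than
forcing a fit, and the pipeline records "no linear regime".

# Damage-layer estimation

"CC scores level off beyond ~30 nm" is made explicit with a hinge (ramp–
plateau) regression on per-tomogram-normalised scores
($\mathrm{CC}/\mathrm{CC_{max}}$, maximum exactly 1 in each tomogram):

$$\mathrm{cc}(d) = c_\text{surface} + (c_\text{plateau} - c_\text{surface})
\cdot \min(d, d_\text{break}) / d_\text{break}.$$

The objective is piecewise smooth in $d_\text{break}$, so the breakpoint is
scanned on a fixed grid (default 1-nm steps over 5–80 nm, matching the
reporting precision) with the two linear parameters solved in closed form at
every grid point; no gradient method, no local minima. Uncertainty comes
from a seeded percentile bootstrap (default 200 resamples). A hinge must
beat a constant fit by an F-like criterion
$F = \frac{(SSE_0 - SSE)/2}{SSE/(n-3)} \ge 4$ — two extra parameters, a
conventional "clearly better" level — otherwise the result is flagged
`no_damage` with the breakpoint reported at the grid minimum. The criterion
threshold is a free parameter because no formal levelling-off test exists
for this quantity.

# Acquisition utilities

`dose_symmetric_scheme()` generates the tilt order: start at the pretilt,
then alternate sides in blocks of `group` consecutive steps. The angle set
is always $\{\text{pretilt} + k\,\text{step}\}$ over $\pm$span; grouping
changes order only. Which side is acquired first is not fixed by the scheme;
`positive_first = TRUE` is the package default and a flag. The default span
of ±60° with a 2° step gives the 61-projection series used throughout.
With a constant exposure the per-tilt dose is total/61 (~120 e⁻/Å² total
here — the per-tilt value is an inference from the stated total).
`exposure_weight()` evaluates the standard critical-exposure attenuation
$\exp(-\text{dose}/(2 N_e(f)))$, $N_e(f) = a f^{b} + c$ with the published
single-particle calibration constants $a = 0.245$, $b = -1.665$, $c = 2.81$
as configurable defaults — they belong to that calibration, not to this
package's data.

# The synthetic generator

`lamella_scenario()` + `simulate_lamella_particles()` emulate what the
analyses need and nothing more:

* a wedge-shaped slab — thickness $t(p) = t_\text{front} + \text{slope}\,p$
  along the front-to-back position — tilted against the tomogram frame by a
  plane, with particles uniform inside the slab and counts Poisson in the
  slab volume. Defaults: 12 tomograms of 800 nm field of view, thickness
  running 43–255 nm across the lamella, plane tilt ~(0.08, −0.05) in voxel
  units, pixel size 4.9 Å, density 8 particles per (100 nm)³ — about 800
  template matches per tomogram, the realistic order for ribosome template
  matching on such fields of view.
* CC scores from a damage model: the ramp (the estimator's own model) or an
  exponential saturation $c_\text{plateau}(1 - \kappa e^{-d/\lambda})$, so
  the breakpoint estimator is exercised both well-specified and
  misspecified. Default ramp: 0.6 at the surface rising to a 0.95 plateau at
  30 nm, Gaussian noise (sd 0.05) truncated to keep scores positive.
* half-map pairs built directly in the Fourier-shell SNR domain:
  $\mathrm{SNR}(k) = \text{scale}\cdot N \cdot e^{-B k^2/2}$, one shared
  band-shaped "structure" plus independent white noise per half-map, so the
  expected FSC is exactly $\mathrm{SNR}/(1+\mathrm{SNR})$ and resolution
  versus $N$ follows the Rosenthal–Henderson law by construction.

What the generator does **not** model: image formation, CTF, the missing
wedge, alignment errors, particle overlap or crowding, and any coupling
between thickness and per-particle SNR beyond what the user encodes in the
scenario. Passing tests therefore demonstrate that the estimators recover
what they are defined to recover under controlled conditions — not that
real lamellae behave like the generator. In particular the simulated
resolution-versus-thickness behaviour is injected, not emergent.

# Problem sizes and numerical choices

The bundled demonstration (`run_demo()`) runs all three analyses on the
default scenario: ~9,600 particles across 12 tomograms, depth groups of 200
particles (sized to the ~2,500 particles that fall in the 140–190 nm
thickness window of the simulated lamella), nested subsets of 250–2,000 per
thickness tertile, 48³ half-map volumes at 1.2 Å, and 100 bootstrap
resamples; it completes in a few seconds and is deliberately desk-scale.
Headline STA resolutions on real data come from hundreds of tilt series and
GPU-weeks of Relion/M refinement; such numbers are outside what any
synthetic desk-scale run can or should reproduce, and the package makes no
attempt to.

Degenerate inputs are refused early with named errors: plane fits with
fewer than three points or collinear (x, y) support (the tomogram is named),
surface estimation below `min_support` or with no bin reaching the plateau
criterion, RH fits with all points at Nyquist, damage fits with fewer than
50 particles. Ties are always broken by stable input order so that every
selection is reproducible; every randomised routine takes an explicit seed
and records it in its outputs, and pipeline CSV/STAR reports carry the seed
and a config hash in their headers.

# Known limitations

* Surface estimation assumes near-uniform particle density through the slab
  thickness; strong depth-dependent depletion (e.g. template matching that
  already discriminates against damaged particles) would bias edges inward.
* Depth error is bounded by the histogram bin width; depths inherit up to
  ~half a bin of systematic error from each surface.
* The hinge model reads gradual (e.g. exponential) damage profiles as a
  breakpoint inside the decay region; the bootstrap CI widens accordingly.
* FSC curves are unweighted and unmasked beyond voxelwise multiplication;
  tight solvent masks with correction are out of scope.
* Front/back labels are consumed as metadata; the package does not classify
  lamella orientation.
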