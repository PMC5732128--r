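---
title: "Calibration-free pinhole SPECT reconstruction with a Monte Carlo forward model"
author: "pinholeMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-free pinhole SPECT reconstruction with a Monte Carlo forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pinholeMC)
```

## The problem

Static multi-pinhole SPECT cameras image a gamma-emitting tracer
(here ^99m^Tc, 140.5 keV) through K pinhole-detector units arranged around
the patient. Reconstructed voxel values are only quantitative — absolute
MBq — if the reconstruction models the photon transport (attenuation,
Compton scatter in the object, collimation) faithfully, and conventional
systems additionally require a measured calibration factor to map counts to
activity.

pinholeMC implements a different route: the *forward* projection inside the
ML-EM iteration is a Monte Carlo simulation that emits photon histories
from the current source estimate and transports them through a density map
to the detectors. Because every history's statistical weight is tied to the
activity the history map represents
(`activity x 1e6 decays/s/MBq x time x photonsPerDecay / nHistories`),
simulated projections are in absolute expected counts, and no calibration
factor exists anywhere in the chain. The *backward* projection is a fast
analytical ray-tracing model. Using different forward and backward system
models is known as dual-matrix reconstruction.

## The update

Classical ML-EM updates voxel j as

    f_new_j = f_j / (sum_i a_ij) * sum_i a_ij * p_i / (sum_k a_ik f_k)

with system matrix elements `a_ij`. The dual-matrix variant replaces `a_ij`
by approximate elements `b_ij` everywhere *outside* the ratio denominator:

    f_new_j = f_j / (sum_i b_ij) * sum_i b_ij * p_i / q_i,

where `q = A f` is realized operationally by the Monte Carlo simulator
(never materialized as a matrix) and `b` by the ray-tracing back-projector.
The source estimate is stored twice: a float activity map (MBq, the
authoritative dataset) and an integer history map whose entries sum to the
per-iteration history budget, re-apportioned from the activities after
every update by largest-remainder rounding. Restarting the simulator from
the integer map is what keeps the counts-activity relation exact across
iterations.

Dual-matrix updates forfeit the monotone-likelihood guarantee of ML-EM;
the per-iteration Poisson log-likelihood proxy is therefore logged for
observation but never asserted to increase.

## The back-projector

For voxel j and unit k the voxel centre is rotated into the pinhole frame
(z' along the pinhole axis), projected through an idealized infinitesimal
pinhole onto the detector plane (`x_d = -M x'`, `y_d = -M y'`,
`M = H / (R - z')`), and spread over an `N_grid x N_grid` cell-centred
lattice covering a square of width `m M` (the magnified voxel footprint).
`N_grid` follows the heuristic

    N_grid = floor(2 + 60 / (1 + (R - z')^0.8) + 0.5),

with the distance in centimetres, giving 62 points per side at zero
distance and 2 in the far limit — an intentionally cheap stand-in for the
inverse-square distance dependence of pinhole sensitivity. `b_ij` is the
number of lattice points landing in pixel i divided by the total number of
lattice points over all K units usable by the voxel (`z' < R`); points that
fall outside the active detector area stay in the denominator (an
alternative denominator that counts only detected points is selectable via
`backproject(..., denominator = "detected")`; the two differ only for
voxels whose footprints leave the detector edge).

The back-projector deliberately ignores attenuation, scatter, the finite
aperture, detector tilt and the incidence-angle dependence of efficiency.
A test pins this: its output is bit-identical under changes of aperture
diameter, collimator attenuation and tilt.

## The forward model

Photon transport samples free paths by Woodcock (delta) tracking against a
majorant built from the densest voxel, which reproduces the exact
heterogeneous free-path distribution while stepping on the mean-free-path
scale rather than the voxel scale. Interactions split into photoelectric
absorption and incoherent scatter by the tabulated channel ratio; Compton
angles are drawn from the Klein-Nishina distribution by rejection sampling
and energies follow `E' = E / (1 + (E/511)(1 - cos theta))`. Mass
attenuation tables (air, water) put the Klein-Nishina closed form behind
the incoherent channel and log-log interpolation of a small reference
photoelectric table behind the photoelectric one; coherent scatter is
omitted throughout (it is nearly elastic and strongly forward at these
energies, and the matched forward model makes the choice self-consistent).

Variance reduction: each history is forced, per unit, into the cone
subtending a disc centred on the pinhole and perpendicular to the line of
sight, with compensating weight `Omega / 4pi`. With the knife-edge
penetration option enabled the disc has four times the aperture diameter so
near-edge paths are sampled; with the default ideal opaque aperture,
directions outside the aperture can never contribute, and the forcing disc
shrinks to the aperture itself — the same estimator in expectation (a test
compares it against fully analog isotropic emission at 3 sigma) with about
16x lower variance. Scatter that would enter the aperture from initial
directions outside the forcing cone is not sampled; this second-order
contribution is small at a ±10% photopeak window, and because projection
generation and reconstruction share the model it does not bias the
self-consistency studies. It does mean the absolute scatter fraction of
real measured data would be underestimated.

The detector is an ideal absorber with an optional Gaussian energy blur
(percent FWHM referenced to 140.5 keV, scaling with sqrt(E)); the energy
window defaults to 140.5 keV ± 10%. Physical decay during acquisition is
ignored (acquisition times are short against the 6-h half-life). The RNG is
counter-based per (history, unit) pair, so projections are bit-for-bit
reproducible and independent of execution order.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grid `N`, `m` | 70, 4 mm | source matrix and voxel size |
| `K`, `R`, `H` | 19, 180 mm, 120 mm | arc units, origin-pinhole and pinhole-detector distances |
| aperture | 5 mm | pinhole diameter (forward model only) |
| detector | 32 x 32, 78.7/32 mm | pixels per side, pitch |
| energy window | 126.45-154.55 keV | photopeak ± 10% |
| `photonsPerDecay` | 0.885 | ^99m^Tc 140.5-keV branching |
| `historiesPerIteration` | study-specific | forward MC budget per update |
| `ratioEpsilon` | 0.1 | ratio guard, fraction of mean nonzero simulated pixel |
| `nIterations` | 20-40 | ML-EM iterations |

The true clinical camera's per-unit geometry is proprietary; the default
here is a synthetic 180-degree arc (uniform R, H, aperture; theta spacing
180/(K-1) degrees; phi = 0) chosen to give a ~19-cm usable field of view
with the stated detector size. Everything is loadable from a flat text
config (`readCameraGeometry`), so no geometry is hard-coded. The ten
laterally tilted detectors of the real system have no published tilt
angles; the default geometry is untilted, the forward model supports tilt
through a general plane intersection, and the back-projector always assumes
a perpendicular detector, consistent with its other approximations.

### The ratio guard

Pixel ratios are `p / max(q, eps * mean(q > 0))`. With desk-scale history
budgets, pixels under-sampled by the finite-history forward projection
(small or zero `q`, nonzero `p`) otherwise produce ratio spikes of order
`1/eps` that the multiplicative update amplifies; with `eps = 0.1` the
spike is bounded by roughly ten times the mean ratio and the iteration is
stable, while converged ratios (~1) are untouched. Very small `eps` values
(1e-3 and below) are only usable with history budgets far beyond what the
bundled studies use — with 3e5 histories per iteration on the torso
phantom the total activity diverged to ~30x truth before this guard was
strengthened.

## The phantom studies

All studies generate their own projections with the package's simulator
and reconstruct with the matched model, which isolates back-projector
normalization and the calibration-free counts-activity chain from camera
model error. Problem sizes are the package's desk-scale choices:

* **Sphere quantification** (`sphereQuantificationStudy`): 9-mL, 1-MBq
  sphere in a non-attenuating medium at the volume centre and two 2-cm
  offsets; 35^3 grid, 1e6 generation histories, 20 iterations at 1e5
  histories each; recovered activity in a VOI of twice the sphere
  diameter. Typical relative errors: 1.5-1.7%.
* **Six-sphere torso recovery** (`torsoRecoveryStudy`): 0.5-16 mL spheres
  at 4.1 MBq/mL on a 50-mm ring in a 45-degree-tilted plane (the mounting
  disk geometry of the physical phantom is not published; these values are
  configurable), inside a water-filled elliptical torso (semi-axes
  150 x 100 mm; the 70^3 x 4 mm grid clips the torso's x extremes, which
  is immaterial for the matched-model comparison); full physics, 2e6
  generation histories, 40 iterations at 3e5 histories. TARCs (VOI =
  physical diameter + 8 mm, i.e. two voxels) land within 10% of unity,
  with the smallest spheres highest — the small-sphere overestimate is the
  expected signature of resolution spill-in plus ratio-noise rectification.
* **Point-source grid** (`pointGridStudy`): 3 x 3 x 3 sources at 20-mm
  spacing, reconstructed one at a time (20 iterations, 5e4 histories),
  Gaussian-filtered (sigma = one voxel, 7^3 kernel), then the
  plane-distance procedure: locate the maximum voxel, average coordinates
  within each true plane, difference adjacent planes. With 4-mm voxels and
  20-mm spacing the recovered distances are voxel-exact.

What passing these studies does **not** show: fidelity to a real camera
(no CZT charge transport, no collimator bulk scatter or backscatter, no
measured-data comparison), robustness to Poisson noise in the measured
projections (generation is noise-free by default; `poissonSampling`
exists but the bundled studies do not use it), or absolute scatter-fraction
accuracy (see the forcing-cone note above).

## Numerical choices and degeneracies

* Voxel membership everywhere is voxel-centre inclusion; no partial-volume
  weighting. Voxelized sphere volumes converge to analytic volumes as m
  shrinks (tested at 4, 2, 1 mm).
* Detector pixel bins are half-open `[lower, upper)` on a grid centred on
  the pinhole-axis intercept; (0, 0) lands in pixel (16, 16) of 32.
* Sampling-grid lattices are cell-centred (`((i + 0.5)/n - 0.5) G_D`);
  edge-inclusive lattices would double-count shared boundaries.
* Voxels at or behind a pinhole plane (`z' >= R`) skip that unit entirely
  (numerator and denominator); voxels with zero denominator over all units
  back-project to 0 and are excluded from updates (their activity stays 0).
* Zero-history voxels with positive float activity are still updated via
  the back-projection — the float dataset is authoritative, and a voxel
  invisible to one iteration's sample is not locked at zero.
* The largest-remainder apportionment breaks remainder ties toward lower
  voxel index, making history maps fully deterministic.
* Iteration i seeds its forward projection with `seed + i`: reproducible
  runs, independent iterations.
* The cardiac shell solves its inner long semi-axis numerically
  (`uniroot`) so the continuum shell volume hits 120 mL exactly; at 4-mm
  voxels the voxelized volume is within ~5% of that.
* OS-EM is deliberately absent: 19 angularly sparse projections make
  subset definition unattractive, and the static geometry gives no natural
  ordering.

## Known limitations

The back-projector models neither the finite aperture nor edge
penetration; an analytic finite-aperture PSF would sharpen resolution
recovery and is the natural next step. High-energy, multi-line
radionuclides (e.g. ^123^I, ^131^I) need collimator and detector physics
this package does not model. Reconstruction cost is dominated by the
forward Monte Carlo; budgets trade ratio-noise bias (which inflates
recovered totals by a few percent when under-sampled) against runtime.
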