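---
title: "Methods: desk-scale virtual imaging for quantitative photoacoustic breast tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale virtual imaging for quantitative photoacoustic breast tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`qpactsim` implements a complete, desk-scale virtual-imaging pipeline for
three-dimensional quantitative photoacoustic computed tomography (qPACT)
of the breast. The physical chain it simulates is:

1. **Light transport.** A short laser pulse at wavelength $\lambda$
   deposits energy in tissue. The local fluence
   $\Phi(\mathbf r, \lambda; \mu_a, \mu_s, g, n)$ is computed by voxelized
   Monte Carlo photon transport.
2. **Photoacoustic generation.** The induced initial pressure is
   $p_0(\mathbf r,\lambda) = \Gamma\, \mu_a(\mathbf r, \lambda)\,
   \Phi(\mathbf r, \lambda)$ with the Grueneisen parameter $\Gamma = 1$,
   the common soft-tissue assumption.
3. **Chromophore model.** Absorption is a linear chromophore sum
   $\mu_a(\mathbf r,\lambda) = \sum_k c_k(\mathbf r)\,\varepsilon_k(\lambda)$
   over oxyhemoglobin, deoxyhemoglobin, water, fat and melanin, so blood
   oxygen saturation is
   $\mathrm{sO_2} = c_{\mathrm{HbO_2}} / (c_{\mathrm{HbO_2}} + c_{\mathrm{Hb}})$.
4. **Acoustics.** Pressure waves propagate through heterogeneous media
   (sound speed, density, power-law attenuation) and are sampled by
   point-like transducers; images are reconstructed by time reversal under
   deliberately mismatched homogeneous assumptions.
5. **Estimation.** sO$_2$ is estimated by linear spectral unmixing, by
   fluence-compensated unmixing, or by a dual-task convolutional network
   that also segments the clinically relevant target structures
   (arteries, veins, viable tumor).
6. **Evaluation.** Vessel/tumor separation by multiscale Frangi
   vesselness, Dice scores, strict-overlap tumor detection counts,
   depth-binned sO$_2$ error and paired mean tumor sO$_2$.

Two study designs are supported. **Study 1** corrupts the *true* $p_0$
volumes with image-domain colored noise — iid sensor noise mapped through
time reversal — isolating estimation behavior from reconstruction
artifacts. **Study 2** runs the full acoustic forward simulation on
heterogeneous media, adds sensor noise, and reconstructs by time reversal
assuming the water sound speed, uniform density, no attenuation and a
coarser grid (voxel ratio 1.2, mirroring a 0.25 mm to 0.3 mm mismatch),
so the estimators face realistic aberration artifacts.

# The synthetic phantom generator

`make_breast_phantom()` builds a hemispherical breast (chest wall at the
z = 0 plane) in a water bath:

* **Skin.** An epidermis/dermis shell (defaults 0.15 mm / 1.35 mm). When
  the epidermis is thinner than one voxel it is rasterized as a single
  voxel layer and the melanosome volume fraction is scaled by
  `epidermis_mm / voxel_size`, preserving the areal melanin content so
  the effective skin-tone absorption is grid-independent. Fitzpatrick
  tones 1–6 map to monotone melanosome volume-fraction ranges (packaged
  constants table).
* **Interior composition.** A smoothed Gaussian random field with a
  central bias is thresholded so the fibroglandular volume fraction
  matches the BI-RADS density type (A/B/C/D = 0.07/0.25/0.50/0.75).
* **Vasculature.** Independent artery and vein trees grown by stochastic
  branching (random bifurcations, child radius ratio $2^{-1/3}\approx0.79$,
  minimum-radius cutoff) and rasterized as capsules. Root/minimum radii
  default to 1.2 / 0.6 mm and the step length and segment budget scale
  with the breast radius, keeping the vascular volume fraction in the
  physiologic few-percent range *and* keeping vessel diameters at 2–5
  voxels on desk grids — the regime in which the Hessian-based vesselness
  protocol is meaningful. Arteries draw sO$_2$ from 0.92–0.98, veins
  from 0.60–0.75 (disjoint ranges, so the artery–vein ordering is an
  invariant).
* **Tumors.** An ellipsoidal viable region with procedural spiculation
  (clamped smooth noise on the rim radius), a necrotic core strictly
  inside it and an angiogenesis shell with elevated blood volume
  fraction. Placement ("middle" at 0.4 of the breast radius below the
  chest plane, or "posterior" adjacent to the chest wall) searches for a
  site with minimal vessel overlap, and the growing mass *displaces*
  vasculature in its clearance zone (vessel voxels within the spiculated
  bound plus two voxels revert to fat). This mass-effect rule is what
  guarantees, deterministically, that the tumor forms its own connected
  component for the rule-only post-processing pipeline — the desk-scale
  stand-in for the manual refinements a human operator would perform.
* **Hemoglobin bookkeeping.** `thb = blood_vf * blood_thb_mM` with a
  whole-blood total heme concentration of 2.33 mM (150 g/L hemoglobin).
  Vessel voxels are pure blood (`blood_vf = 1`, no water/fat terms), so
  unmixing ground truth is exact there.

Chromophore spectra and per-tissue baseline properties ship as versioned
CSVs under `inst/extdata/` (hemoglobin molar extinctions from the
standard Prahl compilation, water from Hale & Querry, lipid from van
Veen, melanin from the Jacques melanosome model; scattering, acoustic
speed/density/attenuation from standard tissue-property compilations).
Users can substitute their own tables to audit provenance.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* relevant to the
estimation problem: tissue-class geometry, disjoint arterial/venous
saturations, density-type composition, skin pigmentation, tumor
subregions, and voxelwise optical/acoustic property maps. It does not
reproduce mesh-based anatomy, ductal structure, measured vessel
morphometry, or the exact property distributions of any deposited
phantom ensemble. Passing tests therefore demonstrate correctness of the
pipeline's physics and protocol logic under controlled conditions, not
clinical performance on real anatomy.

# Numerical choices

**Monte Carlo.** Step lengths are sampled from the local attenuation
$\mu_t$; absorption uses continuous weighting (the packet deposits
$\mu_a/\mu_t$ of its weight per collision); scattering is
Henyey–Greenstein with the local $g$; Russian roulette below weight
$10^{-4}$ with survival factor 10; fluence is the track-length estimator
(weight × path length / voxel volume, per unit delivered energy). The
energy ledger (launched = absorbed + escaped + killed − roulette boost)
closes to better than $10^{-6}$ by construction and is asserted per run.
Refractive-index boundaries are matched — no Fresnel reflection or
refraction — because the acceptance surface does not require internal
reflection and the imaging geometry is index-matched by the water bath;
the $n$ map is carried for future use. Validation is against closed
forms: Beer–Lambert decay in a non-scattering slab (within 2% at $10^6$
photons) and the diffusion Green's function
$\Phi(r) = e^{-\mu_{\mathrm{eff}} r} / (4\pi D r)$ in a high-albedo
medium (within 10% for $r \in [2,6]$ mm), plus $1/\sqrt{N}$ error
scaling.

**Acoustic solver.** First-order coupled pressure/velocity/density
equations solved pseudospectrally with k-space-corrected
(sinc$(c_{\mathrm{ref}} k \Delta t / 2)$), spatially staggered spectral
derivatives, heterogeneous $c$ and $\rho$, and a split-field absorbing
boundary layer of 10 voxels ($\propto$ quartic ramp). The time step
obeys CFL $\le 0.3$ (violations are rejected before stepping).
Transducers snap to nearest voxel centers. Power-law attenuation is
applied as a per-trace frequency-domain filter
$\exp(-\alpha_0 f^{y} d / 8.686)$ with medium-averaged $\alpha_0, y$ and
the source-centroid path length — a deliberate surrogate for the
fractional-Laplacian absorption operator that preserves the
unmodeled-attenuation phenomenon of Study 2 at far lower complexity.
Time reversal re-emits the time-reversed traces as Dirichlet pressure
sources at sensor voxels of a homogeneous model medium and returns the
final-time field; duplicate snapped positions are collapsed (counted and
reported). These choices are validated by travel-time, ring-geometry
disc reconstruction (Pearson r ≥ 0.95) and localization checks.

**Unmixing.** Joint three-wavelength least squares on the
(HbO$_2$, Hb) extinction matrix; the unknown common scale cancels in the
saturation ratio. Negative concentration solutions are clipped at zero;
voxels whose total concentration falls below $10^{-12}$ of the volume
maximum are marked invalid rather than assigned a ratio. Singular
extinction systems are rejected when the matrix is formed; the condition
number of the packaged 3×2 system (~3.3) is attached to the spectra
object.

**Network.** The dual-task estimator is a residual encoder–decoder with
one residual block per level (two 3×3×3 convolutions, leaky ReLU 0.1,
1×1×1 shortcut), 2×2×2 max pooling, channel squeeze-excitation plus a
single-channel spatial gate at the bottleneck, two mirror decoders with
2×2×2 stride-2 transposed convolutions and skip concatenation, and
sigmoid 1×1×1 heads. It is implemented directly in R with explicit
adjoints for every layer (convolutions run as compiled direct kernels);
backpropagation is verified against finite differences in the test
suite, which is the strongest available correctness guarantee for a
hand-written training loop. The loss is
$L = L_{\mathrm{reg}} + \eta L_{\mathrm{seg}}$ with voxel-weighted MSE,
voxel-weighted binary cross-entropy and a smoothed Dice term; voxel
weights are 10 on target-structure voxels and 1 elsewhere, and $\eta$
ramps linearly over the first 20% of epochs — stated approximations
where exact weighting and curriculum schedules were not available to
this implementation. Training uses ADAM; the reference step size is
$10^{-5}$ at full scale, while toy-scale runs use $3\times10^{-4}$,
chosen once from a convergence scan of the single-batch overfit problem
(smaller steps stall in 200 steps; much larger ones oscillate).
Augmentation rotates samples about z by random multiples of 18°,
matching the 20-fold illumination symmetry; masks rotate
nearest-neighbor, continuous maps bilinearly.

**Evaluation.** Depth is the Euclidean distance transform (exact,
Felzenszwalb) from the water–tissue interface, used consistently for the
15 mm segmentation shell, the 3 mm depth bins and the 0.6 mm superficial
skin exclusion. Vessel/tumor separation follows the standard
formulation of the Frangi filter (Gaussian-derivative Hessians,
eigenvalues sorted by magnitude, $\alpha = \beta = 0.5$, structureness
scale set from the smallest scale, scales {1,2,3} voxels); components of
the opened segmentation are vessels iff *strictly* more than 50% of
their voxels carry evidence above an absolute threshold of 0.08, a value
chosen once so that isolated tubes and spiculated tumor-scale blobs from
the generator's geometry regime fall on opposite sides with margin
(verified against the scikit-image reference implementation on identical
masks). Tumor detection uses the strict >500-voxel overlap rule; on
grids other than 0.25 mm the threshold scales with the instance volume
to keep the 500/3808 overlap fraction. Morphological opening uses a
radius-1 cross, once.

# Desk-scale study conditions

The full-scale conditions (0.25 mm grids, 20×5 beams on a 145 mm shell,
108 elements × 480 views at 20 MHz, 320 training pairs, 600 epochs) are
expressible in the configuration objects but are not the defaults. The
shipped study conditions use 48³ grids of 0.5 mm voxels, a 10 mm-radius
breast, 24×16 transducer positions with CFL-derived sampling, 2×10⁴
photons per wavelength, and small paired cohorts. Structure sizes scale
with the grid so that the *ratios* that drive the protocol (vessel
diameter per voxel, tumor radius per voxel, detection overlap fraction)
stay in the regime of the full-scale design; in particular the desk
tumor uses a 73.6 mm³ viable region (≈5 voxel radius) because the
protocol's tube/blob discrimination degenerates below ≈4 voxels radius.
The toy network (3 levels, 8 base channels) trains on 32³ volumes in
minutes on one CPU; the headline full-scale numbers of a 600-epoch
multi-GPU model are out of scope and not claimed.

# Known limitations

* The fluence-compensated baseline cannot correct intravascular
  self-screening (spectral distortion accumulated *inside* a vessel), so
  its arterial bias shrinks less than its venous bias; this mirrors the
  depth-dependent residual error such baselines show at full scale.
* The attenuation surrogate is a per-trace filter, not a propagating
  absorption operator; dispersion is neglected.
* The time-reversal variant is a single final-time snapshot without
  iterative refinement.
* Rule-only post-processing replaces manual refinement; borderline
  components (vesselness evidence near 50%) can flip class on other
  geometries.
* Monte Carlo ignores refractive-index mismatch (no internal
  reflection), which would raise fluence near boundaries by a few
  percent in mismatched media.
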