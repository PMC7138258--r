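---
title: "Context-encoding fluence estimation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-encoding fluence estimation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The quantification problem

A photoacoustic (PA) signal is proportional to the locally absorbed optical
energy,

$$S(v) \propto H(v) = \mu_a(v)\,\Gamma(v)\,\phi(v),$$

where $\mu_a$ is the absorption coefficient, $\Gamma$ the Grueneisen
(thermoelastic) coefficient and $\phi$ the light fluence. The quantity of
clinical interest is $\mu_a$ (and, across wavelengths, blood oxygen
saturation), but the measured image confounds it with $\phi$, which depends
on the optical properties of *all* surrounding tissue. cepaq treats fluence
recovery as a supervised learning problem on voxel-level features:

1. For a fixed hardware setup, a **fluence contribution map** FCM$[v](v')$
   is precomputed per imaging-plane voxel $v$: the fraction of Monte Carlo
   photons traversing $v$ (in homogeneous reference tissue, absorption
   0.1 cm$^{-1}$, reduced scattering 1.5 cm$^{-1}$) that also traversed
   $v'$. It summarizes how light reaches $v$.
2. The **context image** CI$(v)$ is a 12 x 12 two-dimensional histogram of
   the tuples $\{(S(v'), \mathrm{FCM}[v](v')) : \mathrm{FCM}[v](v') >
   \epsilon\}$, both axes log10-scaled. Values above an axis's upper bound
   (255 a.u. for signal, 0.1 for the FCM) are folded into the top bin;
   values at or below the lower bound are dropped.
3. A **random forest** (100 trees, bootstrap, all features per split, grown
   to purity) regresses the **fluence correction**
   $\phi_c(v) = \phi(v)/\phi_h(v)$ from CI$(v)$, where $\phi_h$ is the
   fluence simulated once under the homogeneous background assumption. The
   fluence estimate is $\hat\phi = \hat\phi_c\,\phi_h$, and absorption
   follows by inverting the signal model,
   $\hat\mu_a = S/(k\,\Gamma\,\hat\phi)$.

For oxygenation, per-wavelength CIs at 750/800/850 nm either (a) feed
per-wavelength fluence regressors whose corrected signals are unmixed by
non-negative least squares against the shipped hemoglobin spectra
("CE-corrected unmixing"), or (b) are concatenated into one 432-vector and
regressed directly on sO2 ("functional" mode).

## The in-silico world

Everything is generated internally, so the whole method is testable end to
end without external data.

* **Grid**: 64 (lateral) x 47 (depth) x 62 (scan) voxels at 0.6 mm; light
  enters at depth 0 and the imaging depth reaches 28.2 mm.
* **Vessels**: centerlines advance one voxel per scan slice and wiggle by a
  random walk $r_i = r_{i-1} + \eta a_i$ with per-vessel
  $\eta \sim U(0, 0.2)$ and per-step, per-component
  $a_i \sim U(-0.2, 0.2)$ mm, so the per-component step never exceeds
  0.04 mm — vessels are near-straight tubes with random pose, which is what
  the stated step bounds imply. Voxels within the radius of any centerline
  segment are vessel-labelled; absorption maps are Gaussian-blurred
  (sigma 0.6 mm, reflective boundaries — the mean is preserved exactly) to
  emulate partial-volume effects.
* **Designs**: seven named datasets vary vessel radius (0.5–6 mm),
  vessel absorption (1–12 cm$^{-1}$), vessel count (1–7) and background
  absorption ($10^{-4}$–0.2 cm$^{-1}$) inside canonical bounds; the
  multispectral design (one carotid-like vessel of radius 2.3–4 mm,
  homogeneous sO2) derives absorption from hemoglobin extinction at
  150 g/L, blood volume fraction 1 in vessels and 0.005 in background plus
  a constant non-hemoglobin baseline calibrated so background absorption is
  0.1 cm$^{-1}$ at 800 nm (reference oxygenation 70%).
* **Signal**: $S = \mathrm{clip}(k\,\mu_a\,\Gamma\,\phi,\,0,\,255)$ with
  $\Gamma \equiv 1$ (it cancels in every relative quantity). The global
  scale $k$ is calibrated once per setup so the homogeneous background
  slice has mean signal 4.2 a.u., anchoring the dynamic range to the
  measured intrinsic background statistics; clipping at 255 (rather than
  per-image rescaling) keeps CIs comparable across images.
* **Noise**: three added levels — 2%, 10%, 20% multiplicative Gaussian
  after additive Gaussian (0.125 ± 0.125), (0.625 ± 0.625),
  (1.25 ± 1.25) a.u. — applied additive-first, then clipped at zero.
  Level 0 is the simulation-intrinsic Monte Carlo noise.
* **ROI**: vessel voxels with contrast-to-noise ratio
  $(S - \mathrm{avg}(b))/\mathrm{std}(b) > 2$ (strict), computed against a
  structure-free background slice. The ROI is derived from the pre-noise
  signal so the evaluation stratum is identical across noise levels.

## Monte Carlo light transport

Each scan slice is simulated as an independent 2-D $(x, z)$ problem — the
scanned-volume geometry is translationally compounded, and 3-D transport is
out of scope by design. Photon packets launch from a collimated line source
spanning the full lateral width (the reference linear-probe illumination; a
pencil and a slab source exist for validation), hop with free paths sampled
from the local attenuation, scatter isotropically with
$\mu_s = \mu_s'/(1-g)$ and $g = 0$ (similarity relation; fluence depends on
$\mu_s'$ to first order), deposit $w\,\mu_a/\mu_t$ per collision, and
undergo Russian roulette below weight $10^{-4}$ (survival 0.1). An exact
weight ledger (launched + roulette gain = deposited + exited + roulette
loss) is asserted to $10^{-9}$.

**Estimator choice.** The default fluence estimator is *track-length*
(weighted path length per voxel area), not the collision/deposition
estimator: it is unbiased for the same quantity, has severalfold lower
variance (which is what makes ~1% median errors reachable at reduced photon
counts), and is defined where $\mu_a = 0$. The deposition estimator remains
available and the two agree within Monte Carlo error; scattering-free
transport reproduces Beer–Lambert attenuation within 3 analytic standard
errors at every depth.

**FCM bank.** All 3008 per-voxel FCMs of the imaging plane are accumulated
in a single shared photon pass (pairwise traversal counts), stopping when
the worst-covered voxel reaches its hit quota; each photon is counted at
most once per voxel, so FCM$[v](v) = 1$ and all values lie in $[0, 1]$. The
bank is tied to the hardware setup by a configuration hash and refuses to
load against a different setup.

## Numerical and design choices

* **Binning**: base-10 logs; right-closed intervals $(e_i, e_{i+1}]$, so a
  value exactly on an interior edge goes to the lower bin; upper overflow
  into the top bin; at/below the lower edge dropped. The encoder and the
  test oracle share these conventions exactly.
* **Neighbourhood threshold $\epsilon$**: not stated by the reference
  protocol, which set CI/forest parameters by grid search on a separate
  dataset. Following that protocol on a held-out tuning dataset (its own
  seed, never reused in any benchmark), ROI median fluence error fell
  monotonically from 105% to 30% as $\epsilon$ grew from $10^{-4}$ to
  $3 \times 10^{-2}$: concentrating the 12 FCM bins on the dominant
  illumination cone resolves the in-vessel fluence gradient far better than
  spending most bins on the low-contribution periphery, whose counts are
  nearly constant per target voxel. The default is $\epsilon = 0.03$
  (all-voxel error was flat across the sweep).
* **Forest**: authored in compiled code (no forest package ships in the
  target environment); exact CART splits over per-feature distinct-value
  bins (quantile bins only above 256 distinct values — CI counts are small
  integers, so splits are exact in practice), bootstrap, all features per
  split, grown to purity, prediction = mean over trees, deterministic under
  a fixed seed. Serialized models round-trip bitwise.
* **Balancing**: background voxels are undersampled (seeded, without
  replacement) to a 1:1 ROI/background ratio; ROI samples are never
  dropped. The multispectral benchmark additionally caps the balanced
  sample count (12,000, preserving 1:1) purely as a runtime knob.
* **Slices**: five equidistant scan slices per volume, both ends included.
* **Quantiles**: type-7 (linear interpolation) for all medians/IQRs.
* **Seeds**: one hierarchy (dataset → item → Monte Carlo → noise →
  balancing), every stream derived by hashing; identical seeds and
  configuration reproduce every report byte for byte.

## What the reduced-scale benchmarks do and do not establish

Full experimental scale (150 training volumes per design, $2 \times 10^6$
photons per training slice, $10^8$ per test slice, $10^4$-hit FCMs) costs
hours to days. The shipped presets scale everything down; the `desk` preset
(full grid, 40 training volumes, $10^5$ photons per training slice,
$10^6$ per test slice, 2000-hit FCMs) is what the acceptance tests run, its
numbers chosen from runtime-budget arithmetic before the benchmarks were
observed. Against the full-scale reference results:

* **All-voxel accuracy transfers**: desk-scale baseline-design median
  relative fluence error is ~1.1% (full scale: 1.0%), and the learned
  correction beats the static homogeneous correction in the ROI by a factor
  of ~20.
* **ROI accuracy does not fully transfer**: desk-scale ROI median error is
  ~13–15% against the 4.2% full-scale reference. Attribution experiments
  (training photons x10: no change; FCM quota x5: no change; training
  volumes up to the full 150: 26% → 19%) show this is not a scale
  artifact of the reduced preset but a property of this package's stated
  world: per-slice 2-D transport with full-width line illumination yields a
  steeper, harder-to-regress in-vessel fluence correction than a 3-D
  simulation world, and its shallower background depth profile
  (std(b) ≈ 1.7 a.u. vs 2.8) admits more dark deep-vessel voxels into the
  CNR > 2 ROI.
* **Error orderings across designs are a full-scale property**: at reduced
  scale the ranking is dominated by coverage demands (10 training radii
  cannot cover 0.5–6 mm), so e.g. the radius-varying design can dominate
  the ROI error ranking instead of the absorption-varying one.
* **Oxygenation**: on depth-axis MIP vessel voxels, CE-corrected unmixing
  reaches ~7–9 percentage points median absolute sO2 error at 40–64
  training volumes (full scale reference: 3.1) and the functional mode
  ~7–14 (reference: 0.8, at 240 volumes and 100x the photons); both beat
  raw-signal unmixing (~15) at every tested scale, and the improvement is
  monotone in training volumes (16 → 32 → 64 gave 15.7 → 9.2 → 6.7 for
  corrected unmixing).

## Known limitations

* The acoustic inverse problem (transducer response, reconstruction
  artifacts) is out of scope; signals are ideal absorbed-energy maps.
* 2-D per-slice transport, matched refractive indices, isotropic
  scattering; no vascular trees or heterogeneous scattering.
* The unmixing basis is two-chromophore (HbO2/Hb); background voxels carry
  a non-hemoglobin baseline and are therefore excluded from the unmixing
  benchmark's evaluation set.
* Absolute signal units are conventional: the scale $k$ anchors the
  background mean at 4.2 a.u. by construction, so absolute signal values
  are matched, not predicted.
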