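# cepaq — context-encoding quantitative photoacoustic imaging

Photoacoustic (PA) imaging measures the pressure response to absorbed
optical energy, `S(v) ∝ μa(v) · Γ(v) · φ(v)`. Recovering the optical
absorption `μa` — and, multispectrally, blood oxygen saturation sO2 — is
blocked by the unknown light fluence `φ`, which depends on all surrounding
tissue. **cepaq** implements a machine-learning route to quantification for
users studying qPAI methods in silico: each voxel's measured-signal context
is encoded against a precomputed *fluence contribution map* (FCM) into a
12×12 log-binned *context image* (CI), and a random forest regresses the
*fluence correction* `φc = φ/φh` (true fluence over the
homogeneous-assumption fluence). Absorption follows by inverting the signal
model; sO2 follows either by non-negative least-squares unmixing of the
fluence-corrected signals at 750/800/850 nm or by direct functional
regression on concatenated multispectral CIs.

The package ships the complete in-silico validation world — random-walk
vessel phantoms with hemoglobin-based optics, a 2-D voxel Monte Carlo light
simulator (fluence maps, FCM banks, exact energy ledger), the three-level
noise model, CNR-based ROI definition, and benchmark orchestration with
reduced-scale presets — so every result is reproducible from a seed with no
external data.

## Worked example

A small end-to-end benchmark (reduced "smoke" preset: 32×24×16 grid, 5
training volumes, 10⁴ photons per training slice):

```r
library(cepaq)

ctx <- prepare_context("smoke", seed = 42)   # φh, FCM bank, k calibration
rep <- run_experiment("DSbase", noise = 0, seed = 42, context = ctx)

rep$er$ce$all$median        # 2.9   median relative fluence error, %, all voxels
rep$er$ce$roi$median        # 12.0  ... vessel ROI voxels (CNR > 2)
rep$er$baseline$all$median  # 14.5  static φh correction, all voxels
rep$er$baseline$roi$median  # 257.1 static φh correction, ROI
```

Reading: with 5 training volumes on a toy grid, the learned correction
estimates fluence to ~3% (median, all voxels) and ~12% inside vessels,
while the static homogeneous correction — the non-learning baseline — is
off by 14.5% and 257% respectively; deep inside an absorbing vessel the
homogeneous assumption overestimates fluence severely, which is exactly the
effect the context encoding corrects. At the `desk` preset (full 64×47×62
grid, 40 training volumes) the all-voxel median reaches ~1.1%, matching the
~1% full-scale reference; ROI behaviour is analysed in the vignette.

The calibration in `ctx` anchors the homogeneous background slice at mean
signal 4.2 a.u. (`ctx$stats$std` was 1.72 a.u. here), which fixes the
CNR > 2 region-of-interest rule.

Lower-level pieces are exported individually: `simulate_fluence()`,
`simulate_fcm()` / `precompute_fcm_bank()`, `encode_ci()`,
`rf_fit()` / `train_regressor()` / `predict_fluence()`,
`reconstruct_absorption()`, `nnls_fit()` / `estimate_so2()`,
`run_oxy_experiment()`. Volumes are exchanged as text-encoded NRRD
(`read_nrrd()` / `write_nrrd()`); a CLI wrapper lives at
`inst/cli/cepaq` (subcommands `phantom`, `fluence`, `evaluate`, `oxy`).

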