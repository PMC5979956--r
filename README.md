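# cordgratio

Quantitative microstructural MRI of the cervical spinal cord in R:
magnetization-transfer-saturation (MTsat) myelin mapping, two-shell NODDI
axon mapping, aggregate MR fiber g-ratio computation, atlas-based tract
metric extraction, and group statistics comparing affected, unaffected and
control spinal-cord sides — the analysis chain used to characterize
degenerative cervical myelopathy, where cord compression causes axonal loss
that conventional T1/T2 imaging cannot see.

The package is aimed at quantitative-MRI methods researchers. Patient data
for this design are not publicly deposited, so `cordgratio` ships a digital
spinal-cord phantom that simulates every input the pipeline consumes (FLASH
volumes with MT saturation, double-angle B1 maps, a 41-volume two-shell
diffusion series, a left/right probabilistic tract atlas, patient/control
cohorts with affected-side axon loss) and retains voxelwise ground truth, so
the full chain is validated as the inversion of a known forward model.

## The models

**Myelin.** Three FLASH acquisitions (PD-, T1-, MT-weighted) are inverted
for an apparent relaxation rate, amplitude and MT saturation:

    R1app = (1/2) (S_T1 a_T1/TR_T1 - S_PD a_PD/TR_PD) / (S_PD/a_PD - S_T1/a_T1)
    Aapp  = S_PD S_T1 (TR_PD a_T1/a_PD - TR_T1 a_PD/a_T1) / (S_T1 TR_PD a_T1 - S_PD TR_T1 a_PD)
    dapp  = (Aapp a_MT / S_MT - 1) R1app TR_MT - a_MT^2 / 2

After double-angle B1 correction, the myelin volume fraction is a linear
calibration MVF = c·δ, with c anchored so that the mean g-ratio of a
homogeneous calibration region equals 0.70.

**Axons.** The two-shell diffusion data (b = 1000/2000 s/mm², 20 directions
each plus b = 0) are fit voxelwise with the three-compartment NODDI model —
Watson-dispersed sticks, a tortuosity-coupled extra-neurite tensor, free
water — for the intracellular fraction Vic and isotropic fraction Viso.

**g-ratio.** Per voxel,

    AVF = (1 - MVF)(1 - Viso) Vic
    g   = sqrt(AVF / (MVF + AVF))

Tract values (fasciculus gracilis, fasciculus cuneatus, lateral
corticospinal tract, left/right) are probability-weighted means at the
analysis vertebral level, and group differences are tested by one-way ANOVA
with Scheffé post hoc comparisons.

## Worked example

Simulate a small cohort with 15% affected-side axon loss and preserved
myelin, run the full pipeline, and look at the affected-vs-control
comparisons:

```r
library(cordgratio)

spec <- cohort_spec(
  n_patients = 6, n_controls = 3,
  laterality = c("left", "left", "right", "bilateral", "left", "bilateral"),
  affected_avf_reduction = 0.15,   # 15% axon loss on affected sides
  mvf_change = 0,                  # myelin preserved
  snr = 30, seed = 7,
  base_config = phantom_config(nz = 1))

res <- run_all(run_config(cohort = spec))

subset(res$stats, metric %in% c("avf", "mvf") &
         group_a == "affected" & group_b == "control",
       select = c(tract, metric, mean_a, sd_a, mean_b, sd_b, p_scheffe))
```

```
                 tract metric mean_a   sd_a mean_b    sd_b p_scheffe
1  fasciculus_gracilis    avf  0.300 0.0140  0.350 0.00924  8.84e-04
4  fasciculus_gracilis    mvf  0.371 0.0360  0.365 0.01948  9.56e-01
10 fasciculus_cuneatus    avf  0.301 0.0109  0.347 0.00993  8.64e-06
13 fasciculus_cuneatus    mvf  0.364 0.0299  0.364 0.01668  1.00e+00
19         lateral_cst    avf  0.301 0.0129  0.351 0.01132  6.32e-06
22         lateral_cst    mvf  0.369 0.0275  0.357 0.02378  7.07e-01
```

The affected sides show clear AVF deficits in
all three tracts (p < 0.001) while MVF never approaches significance — axon
loss with preserved myelin, exactly the contrast the pipeline is built to
detect. `res$cohort_table` holds the per-side tract metrics, and with
`run_config(out_dir = ...)` every intermediate map is written as NIfTI
alongside CSV tables and a JSON provenance record.

A thin command-line wrapper with per-stage subcommands (`simulate`, `mtsat`,
`noddi`, `gratio`, `stats`, `run-all`) is installed at
`inst/cli/cordgratio.R`.

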