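# ctperfusion

Temporal-sampling analysis for brain CT perfusion (CTP), for imaging
scientists and perfusion-software developers who want to study — with fully
known ground truth — how lengthening the interval between dynamic frames
(1.5 s → 3.0 / 4.5 / 6.0 s, by leaving out time points) affects perfusion
maps, ischemic volumetry, thrombectomy decisions, and radiation dose.
Clinical CTP studies of this question cannot share their raw scans; this
package replaces them with a synthetic 4D phantom cohort so every step of
the analysis is reproducible and testable.

## What it computes

Per voxel, the tissue enhancement curve is modeled as
`c(t) = CBF · (a(t − δ) ∗ R)(t)` with arterial input `a`, delay `δ` and
exponential residue `R(t) = exp(−t/MTT)`. The processing core inverts this
by **Tikhonov-regularized deconvolution** on a zero-padded circulant
embedding of the AIF (delay-preserving, solved spectrally for all voxels at
once), producing:

* **CBF, CBV** — normalized to the mean of the full contralateral
  hemisphere (% of contralateral), the side with lower mean Tmax;
* **Tmax** — time of the residue-function maximum, on the acquisition grid;
* **MTT** — CBV/CBF;
* **segmentation** — hypoperfusion `Tmax > 6 s`, infarct core
  `rCBF < 30 %` nested within it; mismatch volume = hypoperfusion − core,
  mismatch ratio = hypoperfusion / core;
* **DEFUSE-3 decision** — treat iff core < 70 mL, mismatch > 15 mL, ratio
  > 1.8, with cases inside precision margins (core 65–75 mL, mismatch
  10–20 mL, ratio 1.6–2.0) excluded from decision comparisons;
* **automated QC** — bolus peak later than 90 % of the window (truncation),
  peak below 8 HU (low CNR), frame-to-first-frame correlation below 0.7
  (motion), plus a stricter uninterpretability rule;
* **agreement statistics** — ICC(2,1), median and SD of volume differences,
  Bland–Altman pairs, per quality stratum and sampling factor;
* **dose bookkeeping** — CTDIvol/DLP/effective dose scaled by the retained
  frame proportion `ceiling(n/f)/n` for the two Siemens reference protocols
  (27 frames/100 mm and 30 frames/90 mm at 1.5 s).

## Worked example

```r
library(ctperfusion)

ph <- build_phantom(phantom_spec(), seed = 42)   # 40 mL core in a 90 mL lesion
ph
#> <ctp_phantom> scenario 'clean', seed 42: core 40.0 mL, hypoperfusion 89.9 mL, brain 502 mL
#> <ctp_series> 27 frames @ dt = 1.5 s (window 39 s), grid 6 x 48 x 48 (z,y,x), voxel 10 x 4 x 4 mm

evaluate_qc(ph$series, ph$masks$brain)
#> <ctp_qc> quality high | peak 15.8 HU at 38% of window, min motion index 0.84

maps <- compute_maps(ph$series, ph$masks$brain,
                     aif_search_mask = ph$masks$brain | ph$masks$artery)
defuse3_decide(volumetry(segment_lesions(maps)))
#>   core_ml hypoperfusion_ml mismatch_ml mismatch_ratio eligible in_margin_zone
#> 1   37.76            87.68       49.92       2.322034    treat          FALSE
```

The recovered core (37.8 mL) and hypoperfusion (87.7 mL) sit within a few
voxels of the 40 / 89.9 mL ground truth, and the case is treat-eligible.
Halving the temporal resolution barely moves the volumes:

```r
maps3 <- compute_maps(decimate(ph$series, 2), ph$masks$brain,
                      aif_search_mask = ph$masks$brain | ph$masks$artery)
defuse3_decide(volumetry(segment_lesions(maps3)))
#>   core_ml hypoperfusion_ml mismatch_ml mismatch_ratio eligible
#> 1   37.44            87.36       49.92       2.333333    treat
```

while the dose drops with the retained frames:

```r
scale_dose(dose_protocols()[3, ], 2)
#>        protocol factor n_frames_retained ctdi_vol  dlp effective_dose dose_reduction_pct
#> 1 somatom_flash      2                14      109 1090           2.39           48.1
```

The full experiment — seeded cohort, all sampling factors, QC
stratification, agreement tables, confusion matrices, dose table — is one
call:

```r
ex <- run_experiment(run_config(n_subjects = 50, seed = 1))
glance(ex)       # headline agreement numbers
autoplot(ex)     # ICC / median / SD versus sampling factor
write_experiment(ex, "run01")
```

A thin shell interface over the same functions lives at
`inst/cli/ctperf.R` (subcommands `simulate`, `sample`, `process`, `qc`,
`dose`, `experiment`).

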