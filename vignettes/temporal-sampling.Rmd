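---
title: "Temporal sampling in brain CT perfusion: model, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal sampling in brain CT perfusion: model, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctperfusion)
```

## The question the package addresses

Dynamic CT perfusion (CTP) of the brain acquires a volume every 1.5 s while
an iodinated contrast bolus passes through the cerebral vasculature. The
radiation dose is proportional to the number of dynamic frames, so acquiring
every second, third or fourth frame (effective sampling of 3.0, 4.5 or 6.0 s)
divides the dose accordingly — provided the derived perfusion maps, the
infarct-core and hypoperfusion volumes, and the treatment decisions built on
them remain stable. `ctperfusion` implements that whole chain as testable
code: a synthetic 4D phantom cohort with known ground truth stands in for
clinical scans, frames are removed by decimation exactly as a scanner would
skip them, and every downstream quantity is recomputed per sampling scheme
and compared against the 1.5 s reference.

## Perfusion model

Per voxel, the baseline-subtracted tissue curve is modeled as

$$ c(t) = \mathrm{CBF}\,\big(a(\cdot - \delta) \ast R\big)(t), $$

where $a$ is the arterial input function (AIF), $\delta$ the arrival delay
and $R$ the residue function. The package uses the exponential residue
$R(t) = e^{-t/\mathrm{MTT}}$ by default (a boxcar option exists): it is the
standard indicator-dilution choice and makes the central-volume theorem
($\mathrm{CBV} = \mathrm{CBF}\cdot\mathrm{MTT}$, i.e. area ratio
tissue/AIF $= \mathrm{CBF}\cdot\mathrm{MTT}$) hold exactly, which the test
suite exploits as an oracle.

Deconvolution inverts this model by Tikhonov regularization. The AIF is
embedded in a circulant operator, zero-padded to twice the window, so that
delayed residue peaks are preserved rather than wrapped — this is what makes
$T_\mathrm{max} = \arg\max_t k(t)$ a delay-sensitive marker, and delay
sensitivity is required because hypoperfusion is defined as
$T_\mathrm{max} > 6$ s. For a circulant operator the SVD filter factors
$\sigma_i^2/(\sigma_i^2+\lambda^2)$ diagonalize in the Fourier basis, so the
solution is computed spectrally for all voxels at once; a test verifies
equality with an explicit dense-SVD solve to $10^{-10}$.

CBF and CBV maps are normalized to the mean of the full contralateral
hemisphere (the hemisphere with lower mean $T_\mathrm{max}$), segmentation
uses the established thresholds — $T_\mathrm{max} > 6$ s for hypoperfusion,
relative CBF $< 30\%$ within it for the core, both strict — and treatment
eligibility follows the DEFUSE-3 perfusion criteria (core $< 70$ mL,
mismatch $> 15$ mL, ratio $> 1.8$) with a measurement-precision margin zone
(5 mL for volumes, 0.2 for the ratio) excluded from decision comparisons.

## Key tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `lambda_rel` | 0.10 | fraction of $\sigma_{max}$ | strongest regularization that still recovers noiseless CBF ratios within 5% and $T_\mathrm{max}$ within one sample; larger values visibly shift $T_\mathrm{max}$ of broad residues late |
| `padding` | 2 | — | circulant embedding length; delays up to the full window stay observable |
| `smooth_fwhm_vox` | 1 | voxel | mild 3D Gaussian pre-smoothing; wider kernels smear the brain surface and arterial voxels into parenchyma at this grid |
| `n_baseline` | auto | frames | pre-contrast frames from the mean-curve rise point, minimum 2 |
| `tmax_threshold` | 6 | s | hypoperfusion definition (strict inequality) |
| `cbf_threshold` | 30 | % of contralateral | core definition (strict inequality) |
| DEFUSE-3 block | 70 / 15 / 1.8, margins 5 / 0.2 | mL, mL, —, mL | decision thresholds and precision margins |
| `ratio_min_core_ml` | 3 | mL | mismatch-ratio agreement restricted to cores above this, at both samplings of a pair |

The $T_\mathrm{max}$ of each voxel is reported on the acquisition grid of the
series being processed, without sub-grid interpolation: the quantization this
produces at coarse sampling is precisely the effect under study. Parabolic
peak interpolation was considered and rejected as default for that reason.

## What the phantom emulates — and what it does not

`build_phantom()` assembles, over a two-hemisphere ellipsoidal brain slab,
per-voxel curves `baseline + tissue_curve(AIF, params) + noise`, with a
designated arterial block (undelayed, full-amplitude gamma-variate bolus),
an optional two-compartment lesion in the left hemisphere (an outer
hypoperfused ellipsoid, delay $>6$ s, and a nested core with relative CBF
well below 30%), and a static smooth "anatomical texture" field that gives
frames the spatial structure the frame-correlation motion index needs.
Class curves are generated on a 0.1 s grid and resampled to the acquisition
grid, so the forward model is not tied to the reconstruction grid.
Target lesion volumes are realized by rank-thresholding the ellipsoidal
distance, making ground-truth mask volumes exact to one voxel.

Chosen study conditions, fixed once at design time:

* **Grid** 48 × 48 × 6 voxels of 4 × 4 × 10 mm (a scaled-down slab: ~960 mL
  of analyzed brain). All cohort experiments in the tests and the acceptance
  script use this size; it keeps a 50-case, four-sampling experiment under a
  minute while leaving 250+ voxels in a 40 mL lesion.
* **Bolus** gamma-variate, arrival 7 s, peak at 11.5 s, arterial amplitude
  300 HU; `flow_scale = 0.025` s$^{-1}$ gives a normal-tissue peak of ~20 HU
  and a mean-brain bolus peak of ~17 HU, comfortably above the 8 HU QC floor.
* **Noise** 0.5 HU Gaussian per voxel-frame. The phantom represents
  reconstructions *after* the heavy spatio-temporal denoising that clinical
  perfusion software applies before deconvolution; raw dynamic CT is far
  noisier, but that stage is proprietary and not modeled.
* **Texture** 12 HU SD, 4-voxel correlation length — enough anatomical
  contrast that rigid shifts decorrelate frames the way patient motion does.
* **Lesion severities** (cohort sampling): core relative CBF 0.08–0.14 with
  prolonged MTT 7–9 s and delay 1–3 s beyond the penumbra; penumbra relative
  CBF 0.45–0.65, MTT 5–7 s, delay 7–10 s. Core volumes are drawn uniformly
  over 0–100 mL (and 15% of cases carry no lesion), so the 70 mL DEFUSE-3
  threshold is straddled; no claim of cohort fidelity is made — the study
  population's lesion-size distribution is not public.
* **Artifact scenarios** mirror the three automated QC rules: `late_bolus`
  shifts the arrival so the mean-brain peak lands at 95% of the window
  (truncation rule fires at $>90\%$), `low_cnr` scales the injection so the
  peak is 5 HU (rule: $<8$ HU), `motion` shifts frames 11–21 in-plane by
  3 voxels (motion-index rule: correlation $<0.7$). The default cohort mix is
  90% clean. A stricter "uninterpretable" rule (zero-variance bolus or motion
  index $<0.3$) stands in for the visual exclusion of fatally flawed scans,
  which cannot be automated faithfully.

The parenchyma mask returned for analysis excludes a one-voxel shell at the
brain surface and a perivascular ring around the arterial block, as clinical
map software masks vessels and CSF partial volume. At 4–10 mm voxels this
matters much more than at clinical resolution: without it, partial-volume
voxels dominate the map statistics.

What passing tests therefore do **not** show about real data: the phantom has
piecewise-constant physiology (no gray/white matter difference, no
within-lesion gradients), exact gamma-variate boluses, stationary Gaussian
noise and purely rigid in-plane motion. In particular, with uniform
per-compartment delays the $T_\mathrm{max}$ quantization at 6.0 s sampling
can be *protected* (pre-onset grid points are never selected), so the growth
of hypoperfusion-volume variability with the sampling factor is weaker in the
phantom than in clinical data; the core-volume variability does grow
monotonically and carries the qualitative finding.

## Numerical choices and degenerate inputs

* Tikhonov penalty: identity by default; a first-derivative penalty is
  available but shifts broad residue peaks later and was not preferred.
* $\lambda = 0$ requests an exact inverse; the operator is checked for
  numerical singularity and the call errors rather than amplifying roundoff.
* An all-zero AIF, an empty brain/AIF mask, an out-of-range baseline count,
  a core mask not nested in hypoperfusion, and a zero-variance frame in the
  motion index are all explicit errors or sentinels (`NA`), never silent.
* Voxels with zero recovered CBF get `MTT = NA` and are excluded from masks.
* Undefined mismatch ratio (zero core): the DEFUSE-3 ratio criterion is
  taken as satisfied when hypoperfusion is positive — the clinically intended
  limit as core $\to 0$; such cases never enter the ratio margin zone.
* Ties in the residue argmax resolve to the earlier sample.
* Dose rounding is half-even by default; the 259 mGy × 15/30 = 129.5 mGy
  cell is the one boundary-sensitive value, and the rounding rule is
  configurable (`half-up`, `half-down`, `none`).
* Margin zones are evaluated on the reference-sampling values. An optional
  symmetric widening for coarser samplings is deliberately not applied by
  default: the appropriate widening procedure is ambiguous, and the default
  keeps the comparison conservative.
* Per-case seeds are derived from the master seed up front, so results are
  invariant to processing order.

## Known limitations

* Relative CBF from regularized deconvolution is biased upward in lesions
  whose MTT exceeds the normal-tissue MTT (sharp residue peaks are attenuated
  more than broad ones, by ~1.3× at the defaults); the lesion severities
  above keep recovered core CBF clearly below the 30% threshold despite this.
  Reported $T_\mathrm{max}$ sits up to two samples late of the true delay for
  broad residues for the same reason.
* The simulation lives in reconstructed-image space: no beam hardening,
  scatter, spiral-mode nonuniform peripheral sampling, or projection-domain
  physics.
* Absolute quantification (mL/100 g/min) is out of scope; all outputs are
  relative or temporal, as in the clinical processing being emulated.
* Equivalence with any proprietary clinical package cannot be claimed; the
  pipeline is self-consistent against its own forward model and oracles.

## Reproducing the experiment

```{r example}
config <- run_config(n_subjects = 50, factors = 1:4, seed = 1,
                     scenario_mix = c(clean = 1))
experiment <- run_experiment(config)
print(experiment)
autoplot(experiment)
write_experiment(experiment, "run01")
```

`scripts/acceptance.R` performs exactly this (plus a 20-case noiseless
mask-recovery cohort and the dose arithmetic) and writes the headline
quantities as JSON.
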