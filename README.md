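# petstand

Post-acquisition intensity standardization of PET images.

## The problem

Voxel values in FDG-PET volumes — activity concentration (AC, Bq/mL) or
standardized uptake value (SUV = AC normalized by injected dose per unit
body weight) — vary substantially across subjects, scans and scanner models
even in perfectly normal tissue. A "normal liver" can mean 3,000 Bq/mL on
one scan and 18,000 on another; SUV removes only part of this. The
variability breaks quantitative thresholds, cross-patient comparison, and
any analysis that assumes PET numbers have a uniform tissue-specific
meaning.

`petstand` is for imaging scientists and pipeline builders who need PET
intensities with standardized numeric meaning: it implements a
histogram-landmark standardization that is calibrated **once** on a cohort
of normal scans with a reference-organ mask (liver or spleen), and then
applied to **any** scan — normal or pathological — with no segmentation
beyond an automatic body-region threshold.

## The method

For an image *I*, landmarks are the global minimum (`p_alpha`, essentially 0
in PET), the body-region median `p_m(I)`, and an upper percentile
`p_beta(I)`. Calibration, from normal scans with a reference organ *O*:

1. map each image linearly from `[p_alpha, p_b]` onto `[0, s_max]` and
   compute `delta_O(b)`, the cohort coefficient of variation of the mapped
   organ mean;
2. choose `beta = argmin_b { delta_O(b) : 90 <= b <= 100 }` (largest b among
   ties) — the cut separating stable normal uptake from the chaotic
   high-uptake tail;
3. set `s_m` = cohort mean of the mapped body medians, and the inverse
   scale factor `1/lambda` = reciprocal of the one-SD-trimmed mean of the
   per-image scale factors `s_max / p_beta(I)`.

Transformation of any image is then `psi = inv_scale * eta`, where `eta`
maps `[p_alpha, p_m] -> [0, s_m]` and `[p_m, p_beta] -> [s_m, s_max]`
piecewise-linearly, extrapolating both tails so the full dynamic range
(including lesions above `p_beta`) is retained and voxel rank order is
preserved exactly. Defaults: `s_max` = 5.00 (SUV) or 50,000 Bq/mL (AC),
percentile grid step 0.1.

The package also provides Gaussian, Z-score and simplified histogram-landmark
baseline normalizers, the evaluation statistics used to compare them
(cohort CV of organ means, repeat-scan mean absolute difference, Welch
inter-scanner comparison), a synthetic body-torso phantom generator that
serves as the test bed, and a command-line interface
(`inst/exec/petstand`: `simulate | calibrate | standardize | suv | baseline |
evaluate`). See the vignette (`vignettes/pet-standardization.Rmd`) for the
full model, parameter rationale, and design notes.

## Worked example

Simulate a 10-subject normal cohort, calibrate an AC standard scale with
liver as the reference organ, and evaluate on the held-out spleen:

```r
library(petstand)

cohort  <- generate_cohort(phantom_config(), n = 10, seed = 1)
vols    <- lapply(cohort, `[[`, "volume")
livers  <- lapply(cohort, function(s) s$masks$liver)
spleens <- lapply(cohort, function(s) s$masks$spleen)

scale_ac <- calibrate(vols, livers, std_config("AC"))
scale_ac
#> <standard_scale> AC  s = [0, 16475.7, 50000]  beta = 95.2  inv_scale = 0.164764  (n = 10, organ = liver)

std <- lapply(vols, standardize, scale = scale_ac)
c(raw_pct = 100 * cv_metric(mapply(organ_mean, vols, spleens)),
  std_pct = 100 * cv_metric(mapply(organ_mean, std,  spleens)))
#>  raw_pct  std_pct
#> 32.67197  6.18896
```

Reading the output: the calibrated upper percentile `beta = 95.2` sits below
the simulated lesion onset (98th percentile of body voxels) — the search
grid stored in `scale_ac$grid` shows `delta_O` at 0.13% for b = 95 versus
6.7% at b = 98 and 17% at b = 99, the sharp rise that marks the chaotic
high-uptake tail. The spleen-mean coefficient of variation drops from 32.7%
(dominated by the simulated scanner gain, U(0.5, 2)) to 6.2%, close to the
5% between-subject biological variability built into the phantoms — the
floor that an intensity transformation should not cross.

The same pipeline from the shell:

```sh
petstand simulate  --out cohort/ --n 10 --seed 1
petstand calibrate --cohort cohort/ --organ liver --modality AC
petstand standardize --image cohort/sub-01_pet.nii.gz \
  --scale cohort/standard_scale.json --out sub-01_std.nii.gz
```

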