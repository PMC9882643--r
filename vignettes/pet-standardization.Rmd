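---
title: "Post-acquisition PET intensity standardization: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-acquisition PET intensity standardization: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petstand)
```

## The problem

Voxel values in FDG-PET volumes — raw activity concentration (AC, Bq/mL) or
standardized uptake value (SUV) — do not carry a uniform numeric meaning
across subjects, scans, or scanner models. SUV,

$$\mathrm{SUV}(v) = \frac{I(v)}{\text{injected dose} / \text{body weight}},$$

compensates for dose and body size but leaves substantial residual
variability from acquisition, reconstruction and physiology. The consequence
is that "normal liver uptake" is a different number in every scan, which
undermines quantitative thresholds, cross-sectional comparisons and
longitudinal response assessment.

`petstand` implements a post-acquisition remedy: a histogram-landmark
standardization in two steps — a **one-time calibration** of a standard
intensity scale from a cohort of normal scans, and a **per-image
transformation** applied to any scan thereafter. After transformation,
comparable normal tissue maps to similar numbers regardless of which scanner
or subject produced the image.

## The model

### Landmarks

For an image $I$, five intensity landmarks anchor everything:
$\min(I)$; the lower percentile $p_\alpha(I)$, pinned to $\min(I)$ (PET
backgrounds are essentially zero, so $\alpha$ is not a free parameter); the
median $p_m(I)$ of the **body region**; the upper percentile $p_\beta(I)$
of the body region at a calibrated percentile $\beta$; and $\max(I)$.

The body region is found by thresholding $I$ at its global mean
(`body_mask()`): whole-torso PET histograms are bimodal with a near-zero
background mode, and the mean separates the modes. The segmentation is
deliberately rough — the median within it is insensitive to boundary errors,
which the test suite checks by eroding ground-truth masks.

Percentiles are linear-interpolation order statistics (the inclusive scheme,
`stats::quantile` type 7). The definition matters only in that it must be
continuous in the percentile, which the grid search below needs; any
consistent scheme yields the same method.

### Calibration

Calibration uses a cohort $\mathcal{I}_c$ of normal scans with a
**reference organ** mask $O$ (liver or spleen — organs with stable, moderate
uptake; high-uptake organs such as brain, heart or bladder are unsuitable).
The masks are needed *only* here, never at transformation time.

For a candidate upper percentile $b$, each image is mapped linearly by
$\lambda : [p_\alpha(I),\, p_b(I)] \to [0,\, s_{max}]$ and the coefficient of
variation of the within-$O$ mean across the cohort,
$\delta_O(b) = \sigma_O(b)/m_O(b)$, is computed (`delta_cv()`). The optimal
upper percentile is

$$\beta = \arg\min_b \{\delta_O(b) : 90 \le b \le 100\},$$

taking the **largest** $b$ among ties (`optimize_beta()`). The rationale:
below the high-uptake tail, $p_b$ is an equally reliable anchor in every
subject and $\delta_O$ is small; once $b$ crosses into intensities dominated
by lesions and outliers, $p_b$ becomes chaotic across subjects and
$\delta_O$ rises sharply. $\beta$ is exactly the cut that separates the two
regimes.

Two more quantities complete the scale. The standard median

$$s_m = \frac{1}{|\mathcal{I}_c|} \sum_{I \in \mathcal{I}_c} \lambda(p_m(I))$$

is the cohort mean of the mapped body medians (`estimate_sm()`). The
**inverse scale factor** $\lambda^{-1}$ restores physical meaning: with
$p_\alpha = 0$ each $\lambda$ is a pure multiplication by
$s_{max}/p_\beta(I)$; factors further than one standard deviation from their
mean are trimmed, and $\lambda^{-1}$ is the reciprocal of the trimmed mean
(`estimate_inv_scale()`). The product is a `standard_scale` object
$(s_{min}{=}0,\, s_m,\, s_{max},\, \beta,\, \lambda^{-1})$, serialized as
JSON — the sole hand-off between the two steps.

Note that during calibration only the *two-landmark* map $\lambda$ can be
used: the three-landmark piecewise map requires $s_m$, which is itself
defined only after $\beta$ is known.

### Transformation

Any image (normal or pathological) is standardized by
$\psi = \lambda^{-1} \circ \eta$ (`standardize()`). The intermediate map
$\eta$ is continuous piecewise-linear through the image's own landmarks:
$[p_\alpha, p_m] \to [s_{min}, s_m]$ and $[p_m, p_\beta] \to [s_m, s_{max}]$,
with both segments extrapolated linearly. Intensities above $p_\beta$ — the
lesion/outlier tail — are therefore *retained*, mapping beyond $s_{max}$ to
an image-specific ceiling; nothing is clipped, and the map is strictly
increasing so voxel rank order is preserved exactly. Only the automatic body
mask of the input is required.

Chained strategies (`run_strategy()`) compose standardization with SUV
estimation, e.g. `"s-AC,SUV"` or `"s-SUV,s-SUV"`. A repeated standardization
step re-estimates the calibration parameters on the already-standardized
calibration cohort, as the iterative scheme requires. In practice the first
application removes nearly all non-standardness and the second is close to
an identity — the package's iteration-stability test quantifies this.

### Evaluation metrics and baselines

Effectiveness is measured on organ means $\mu_O(I)$:

* $CV_O = S_O / M_O$, the cohort coefficient of variation (`cv_metric()`);
* $MD_O$, the mean over repeat-scan pairs of
  $|\mu_O(I_1) - \mu_O(I_2)| / \tfrac{1}{2}(\mu_O(I_1) + \mu_O(I_2))$
  (`md_metric()`) — note the normalizer is the number of *pairs*, so a single
  identical pair gives 0 and a single $(1,3)$ pair gives 1;
* a Welch two-sample comparison of organ means between scanner groups
  (`interscanner_compare()`).

Three comparison normalizers are provided: Gaussian
($I_s(v) = I(v)/\sigma_O(I)$), Z-score
($I_s(v) = (I(v) - \mu_O(\mathcal{I}_c))/\sigma_O(I)$ — the typeset source
formula is ambiguous; the standard subtract-then-divide reading is used), and
a simplified histogram-landmark method (`nyul_calibrate()` /
`nyul_standardize()`): fixed landmarks at the body-region minimum, median and
99.8th percentile, mapped piecewise-linearly to cohort-mean positions,
without reference-organ optimization of the cutoff and without inverse
scaling. It is a reduced, structural comparator — the full multi-landmark
MRI method it abbreviates is out of scope — and its fixed cutoff sits inside
the chaotic high-uptake zone whenever lesions occupy more than 0.2% of the
body, which is precisely the failure mode the optimized $\beta$ avoids.

Both G- and Z-methods need an organ segmentation of *every* image and are
strictly meaningful only inside it; the package normalizes the whole image
and evaluates means within organs only, matching the comparison protocol.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `s_max` (SUV) | 5.00 | SUV | preserves 0.01-SUV discriminability of normal uptake through the mapping |
| `s_max` (AC) | 50,000 | Bq/mL | AC-scale analogue of the same resolution argument |
| `b_low`, `b_high` | 90, 100 | percentile | search interval for $\beta$ |
| `b_step` | 0.1 | percentile | $\beta$ is meaningful to one decimal |
| `sd_convention` | population | — | makes two-image cohorts well defined; sample SD available |
| reference organ | liver | — | stable, uniform, sufficiently large FDG uptake; spleen also supported |

There are no per-image parameters: once calibrated, transformation is fully
automatic.

## The synthetic test bed

No clinical scans ship with the package; `phantom_config()` /
`generate_cohort()` / `generate_repeat_pairs()` produce phantom cohorts with
the statistical structure the method rests on:

* near-zero background and an ellipsoidal body at 2000 Bq/mL — the bimodal
  global histogram that mean-thresholding assumes;
* homogeneous liver (6000 Bq/mL) and spleen (5000 Bq/mL) ellipsoids, each
  scaled per subject by a factor with 5% CV — true biological variability
  that standardization must *not* remove;
* sparse high-uptake lesion foci (20,000–50,000 Bq/mL, 2% of body voxels by
  default) with chaotic per-focus values — deliberately the **only**
  gain-independent cross-subject chaos, isolating exactly the phenomenon the
  $\beta$ optimization exists to excise; their onset percentile
  ($100 \cdot (1 - \text{lesion fraction})$) is recorded in the truth
  record;
* one multiplicative per-scan scanner gain, $U(0.5, 2)$ by default — the
  technical variability standardization *should* remove;
* Gaussian noise with SD proportional to the local mean (a crude stand-in
  for reconstruction noise; Poisson-like models are out of scope).

Every draw is seed-deterministic and accompanied by a truth record (gain,
organ factors, true organ means), so ground-truth comparisons never re-read
voxels. Repeat pairs share anatomy and organ factors up to a small
multiplicative jitter ($\pm 3\%$ by default) and draw independent gains and
noise.

What the phantoms do **not** emulate: anatomy (ellipsoids suffice because
the method sees only histograms and masks), scatter, partial volume,
attenuation, cross-subject histogram *shape* differences beyond
level/gain/lesions, and scanner-specific point-spread behaviour. Passing
tests on phantoms therefore demonstrate the method's mechanics — gain
cancellation, tail excision, landmark stability — not clinical performance.

## Experiment design choices

* **Reference vs test organ.** Cohort experiments calibrate with liver as
  the reference organ and evaluate $CV_O$/$MD_O$ on the held-out spleen.
  Evaluating the reference organ itself would overstate performance: the
  calibrated $p_\beta$ tends to sit inside the reference organ's own
  intensity band, its biological factor cancels, and the residual reduces to
  quantile-estimation noise rather than the biology-dominated residual a
  held-out organ shows.
* **Inter-scanner isolation design.** The two simulated "scanner" groups
  image the *same* subjects under different gain distributions, so the gain
  difference is the only group effect. With independently drawn subjects the
  post-standardization comparison is an exact null-hypothesis test and its
  p-value is uniform — rejections would measure the test's false-positive
  rate, not the method.
* **$\beta$ recovery.** On default cohorts the recovered $\beta$ is checked
  against an exhaustive brute-force grid search and against the lesion onset
  as an upper bound ($\beta \le$ onset $+$ one step). The argmin is *not*
  pinned to the onset itself: wherever $p_b$ falls inside a normal-organ
  band, $\delta_O(b)$ is near-flat and the exact minimizer within that
  plateau is noise-determined. The sharp rise of $\delta_O$ past the onset
  is the meaningful signature.
* **Problem sizes.** Unit tests use 16×20×20 phantoms; cohort experiments
  use the default 24×32×32 grid at 4 mm spacing with cohorts of 8–20
  subjects — large enough for stable organ statistics (~150–700 voxels per
  organ), small enough that the full experiment suite runs in well under a
  minute.

## Numerical choices and degenerate inputs

* Ties in the $\beta$ grid search are resolved to the **largest** percentile,
  with a tiny numerical tie tolerance ($10^{-12}$ absolute plus $10^{-8}$
  relative) so that gain-only cohorts — where every grid point is zero up to
  float roundoff — deterministically select `b_high`.
* If the one-SD trim in `estimate_inv_scale()` would discard every factor,
  the untrimmed mean is used rather than failing.
* Degenerate landmark orderings ($p_\alpha \ge p_m$ or $p_m \ge p_\beta$,
  e.g. constant body regions) are errors by default; `strict = FALSE`
  returns a flagged set for diagnostics.
* Constant volumes cannot be body-masked (empty mask) and are rejected.
* Volumes are stored on disk as 32-bit floats, which carries the 0.01-SUV
  discriminability requirement and the full Bq/mL range with ample margin;
  negative or non-finite voxels are rejected at the I/O boundary.
* With $p_\alpha = \min(I) = 0$ and $s_{min} = 0$, $\psi$ cannot produce
  negative outputs; the implementation asserts non-negativity rather than
  clamping, so a violation surfaces as an error instead of silent clipping.
* Both-constant groups in the Welch comparison are handled explicitly
  (equal means: $t = 0$, $p = 1$) since the generic t-test errors on
  constant data.

## Known limitations

* Calibration assumes normal scans; lesions in the calibration cohort would
  contaminate $\delta_O(b)$ below the intended cut.
* The method presumes $\min(I) \approx 0$; preprocessed volumes with shifted
  baselines violate the pure-multiplication reading of $\lambda$.
* The simplified landmark baseline is a structural comparator only; absolute
  comparisons against the full MRI-style multi-landmark method are out of
  scope.
* Phantom realism is intentionally minimal (see above); clinical validation
  requires clinical data.

## Worked example

```{r example}
cfg <- phantom_config()
cohort <- generate_cohort(cfg, n = 10, seed = 1)
vols <- lapply(cohort, `[[`, "volume")
livers <- lapply(cohort, function(s) s$masks$liver)
spleens <- lapply(cohort, function(s) s$masks$spleen)

scale_ac <- calibrate(vols, livers, std_config("AC"))
scale_ac

std <- lapply(vols, standardize, scale = scale_ac)
raw_cv <- cv_metric(mapply(organ_mean, vols, spleens))
std_cv <- cv_metric(mapply(organ_mean, std, spleens))
c(raw_pct = 100 * raw_cv, standardized_pct = 100 * std_cv)
```

The spleen-mean coefficient of variation collapses from the gain-dominated
raw value to approximately the configured 5% between-subject biological
variability — which is the floor no intensity transformation should cross.
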