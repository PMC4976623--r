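---
title: "Methods: mineral-to-collagen scoring of bone Raman and SORS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mineral-to-collagen scoring of bone Raman and SORS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneraman)
```

## The measurement problem

Bone is a composite of carbonated apatite mineral and a collagen matrix,
and the ratio of the two phases contributes directly to its mechanical
competence. Raman spectra of cortical bone carry both phases in one
measurement: the phosphate ν1 band near 960 cm⁻¹ and the carbonate band
near 1070 cm⁻¹ for the mineral; proline/hydroxyproline (855/875 cm⁻¹),
amide III (~1250 cm⁻¹), CH₂ (~1450 cm⁻¹) and amide I (~1660 cm⁻¹) for
collagen. Two obstacles separate a raw spectrum from a usable
mineralisation measure:

1. **Fluorescence.** Tissue fluorescence puts a broad, intense background
   under the Raman bands.
2. **Overlayers (in vivo).** Measured transcutaneously with spatially
   offset Raman spectroscopy (SORS), the collected light mixes bone with
   skin and lipid signals that overlap the collagen bands, so the bone
   spectrum must be unmixed before any ratio is meaningful.

The package implements one pipeline for excised bone (no overlayer) and
one for in vivo SORS measurements, sharing the scoring and diagnostic
stages.

## Background removal

`remove_background()` is the iterative modified polyfit: fit a degree-*p*
polynomial by least squares, clamp the working spectrum to the fit
wherever it exceeds it, refit, and stop when the fitted baseline changes
by less than `tol` (default 1e-4, relative) or after `max_iter` (100)
rounds. Because Raman bands only ever add intensity, the clamped refits
settle onto the fluorescence under the bands. The default degree is 5,
the common choice for the 800–1800 cm⁻¹ fingerprint region; on synthetic
spectra with known band heights a degree-6 fit visibly bites into the
amide I envelope and attenuates recovered cohort differences, while
degree 5 removes polynomial baselines exactly (they are exactly
representable) and recovers isolated band heights to better than 2%.
The corrected spectrum may contain small negatives; that is expected and
harmless downstream.

## Band intensities and normalisation

"Intensity" of a named band means its *peak height* inside an inclusive
wavenumber window; an integrated-area variant exists behind
`band_intensity(type = "area")`. Height is robust to trimming boundaries
and matches how normalisation bands are used in practice. Normalisation
(`normalize_to_band()`) divides the whole spectrum by that height, so it
is idempotent and scale-invariant. The pipeline uses three reference
bands: phosphate ν1 (950–970 cm⁻¹) for excised spectra, the lipid band at
1299 cm⁻¹ (1289–1309) for raw in vivo spectra, and the carbonate band
(default window 1050–1090 cm⁻¹ — the band is named in the literature
without limits, so the window is configuration) before PCA.

## Despiking and the weak-mineral filter

In vivo measurements are stacks of 60 × 1 s accumulations. Cosmic rays
hit single channels of single frames, so `despike()` compares
accumulations channel-wise and excludes values above
`median + 8·MAD` before averaging — the same outlier-comparison idea
SORS detectors apply on-line. The multiplier 8 is deliberately loose:
with ≥ 10 frames a genuine cosmic spike is hundreds of MADs out, while
the signal itself never is.

After lipid normalisation, spectra whose ν1 intensity falls below 0.45
carry no usable mineral signal (the band loses its shape and sinks into
neighbouring envelopes) and are discarded; exactly-at-threshold spectra
are kept. Subjects left with fewer than 5 spectra are flagged rather than
dropped.

## BTEM: recovering the bone spectrum per subject

For each subject, the surviving spectra form an m×n matrix whose leading
right singular vectors span the chemically meaningful signal
(`compute_basis()`, no mean-centering — centering would destroy the
non-negative structure pure components must have). Band-target entropy
minimisation then searches the span of the first five vectors for the
*simplest* spectrum that contains the targeted ν1 band:

$$F(t) = H(s(\hat{x})) + \gamma \sum_j \min(s(\hat{x})_j + \delta,\, 0)^2
       + \gamma \sum_j \max(s(\hat{x})_j - c,\, 0)^2$$

with $\hat{x} = Vt$ rescaled at every evaluation so its maximum in the
959–963 cm⁻¹ window is 1, and $H$ the Shannon entropy of the
first-difference distribution (`derivative_entropy()`): few, smooth
features give low entropy; mixtures give high entropy.

Three implementation choices matter and are worth recording:

* **Resolution-matched smoothing $s(\cdot)$.** Spectra are sampled at
  1 cm⁻¹ but the instrument resolution is ~8 cm⁻¹. At realistic noise the
  raw first-difference distribution is dominated by sub-resolution noise
  — candidate spectra become indistinguishable and the objective prefers
  whichever candidate carries the least basis noise, not the least
  mixing. Evaluating all terms on a 15-channel boxcar-smoothed copy (and
  pre-smoothing each subject's stack with a 7-channel boxcar before the
  SVD) restores the feature-level entropy ordering the method relies on.
  The reported estimate itself is the unsmoothed combination.
* **Negativity deadband $\delta = 0.02$.** The basis carries noise, so
  even the true pure component reconstructs with small negative wiggles.
  Penalising them at full weight pushes the optimum toward solutions
  padded with a smooth positive "cushion" of the other components. A
  deadband of 2% of the target height absorbs the wiggles while genuine
  over-subtraction (broad dips of 5–20%) is still penalised at
  $\gamma = 10^4$.
* **Target-dominance cap $c = 3$.** Rescaling by the in-window maximum
  cannot distinguish a real targeted band from the tail of a much larger
  feature elsewhere; without a cap, a spectrum that is essentially pure
  soft tissue (with 50× features outside the window) can minimise the
  entropy. Requiring no feature to exceed 3× the target height rejects
  these degenerate optima and is far above anything a ν1-normalised bone
  spectrum contains (its largest other feature is ~1.1).

The optimiser is Nelder–Mead multistart: the projection of a unit peak at
the target centre onto the basis, every signed basis direction, and eight
seeded random unit vectors; all starts are screened cheaply and the best
three polished to `reltol` 1e-8, repeating until no further improvement.
Directions with singular values below 1e-10 of the leading one are
dropped first (they are numerical fill, not signal). Because the entropy
objective is insensitive to smooth positive offsets, the in vivo pipeline
applies one final background correction to each subject's estimate before
trimming.

Each subject is decomposed independently — no pooling — so the extraction
cannot absorb or create between-subject (health-related) variance.

## PCA collagen scoring and reconstruction

After trimming (987–1800 cm⁻¹ for excised spectra; 987–1540 cm⁻¹ in vivo,
which also removes the amide I band — SORS photons travel long tissue
paths and wavelength-dependent absorption corrupts that region) and
carbonate normalisation, `fit_collagen_pca()` runs a mean-centered SVD
without variance scaling (all channels share units after normalisation).
The first loading is oriented to have positive mean over the 1200–1300
cm⁻¹ amide III window, so larger scores always mean more collagen; the
remaining loadings get a deterministic largest-element sign convention,
making results reproducible across platforms. Group averages are
reconstructed as rank-1 objects, `mean + (mean cohort score)·loading₁`.

The percent mineralisation difference between two carbonate-normalised
spectra is computed from $R = I_{\text{carb}} / \int_{\text{collagen}} I$
as $100\,(R_a/R_b - 1)$, which for carbonate-normalised inputs reduces to
the inverse ratio of collagen-region integrals (trapezoidal). The
carbonate reference window is excluded from the integrand: the nominal
collagen region (default 988–1800 cm⁻¹, 988–1540 in vivo) contains the
carbonate band, which is mineral signal, and leaving it in dilutes a true
difference δ by 5–15% of δ — enough to matter at the precision the
package is tested to. The window itself remains configuration: on real
bone, different band subsets are known to give answers spread over
several percentage points.

## Diagnostics

Group comparisons use the two-sided Welch unequal-variance t-test on
per-subject mean scores (a permutation variant is available as a
robustness check); bone heterogeneity on the millimetre scale makes
single-spectrum scores scatter widely, and averaging per subject before
testing mirrors how a diagnostic would be used. Sensitivity at fixed
specificity assumes normal within-group score distributions: the
threshold sits $z(\text{spec})$ control standard deviations from the
control mean on the diseased side, and sensitivity is the diseased tail
beyond it — exactly $1-\text{spec}$ when the distributions coincide. The
required sample size uses the standard normal-approximation formula at
α = 0.05 and 80% power (the power convention is a parameter, and the
formula's inputs are always echoed in the output, because the answer is
meaningless without them).

## The synthetic-data generator

The generator exists because no raw spectra are deposited for studies of
this kind; it emulates the statistical structure the analysis assumes.

* **Components.** Pseudo-Voigt bands (0.5 Lorentzian fraction — no
  lineshape is standard-enough to assume otherwise) on an 800–1800 cm⁻¹,
  1 cm⁻¹ axis: bone mineral (ν1 960, carbonate 1070), collagen (855, 875,
  amide III 1250, CH₂ 1450, amide I 1660), lipid (1299, 1440), and a
  broad-banded generic skin matrix. Carbonate position and the skin
  spectrum are implementation choices, not literature facts.
* **Ratio model.** The mineral-to-collagen ratio is a single scale factor
  on the mineral component; each subject draws a true ratio
  (between-subject sd), each spectrum a site-level ratio around it
  (within-subject sd), truncated at 10⁻³ of the mean so cohort sizes stay
  exact.
* **Excised defaults** (`cohort_spec()`): between-subject sd 0.02,
  within-subject sd 0.05, detector noise sd 0.01, order-5 random
  positive fluorescence baselines of unit scale. These were chosen once
  so that a 5.5% cohort difference reproduces the qualitative findings
  reported for fractured vs control femoral-neck bone: heavily
  overlapping per-spectrum scores that are nevertheless extremely
  significant at n = 150 + 150, per-subject significance around the
  percent level, and ~75% sensitivity at 90% specificity.
* **In vivo defaults** (`sors_config()`, `synthesize_invivo_study()`):
  soft-tissue weight drawn per measurement from 0.3–0.7 (the sampled
  soft fraction varies with probe site, spatial offset and skin
  thickness — and without mixing-ratio variation the per-subject
  decomposition problem is rank-deficient and unsolvable in principle),
  amide I attenuation 0.5 above 1540 cm⁻¹, 60 × 1 s accumulations with
  per-frame noise sd 0.05, Poisson cosmic spikes, and a fluorescence
  baseline drawn once per measurement — fluorescence originates in the
  static tissue under the probe, so successive frames share it.
  Within-subject ratio sd is 0.02, smaller than the excised value,
  because diffuse SORS photons volume-average centimetres of cortex;
  this is also the regime in which extracting *one* bone spectrum per
  subject is well-posed — with strong measurement-to-measurement
  composition variation, curve resolution legitimately resolves mineral
  and collagen separately instead.

**What passing tests do and do not show.** The generator's bands are
smooth, its noise Gaussian and white, its baselines exactly polynomial,
and its mixing exactly linear. Real spectra add wavenumber-calibration
drift, detector etaloning, non-polynomial fluorescence, photobleaching,
and biological covariates (age, sex, treatment). Passing the end-to-end
recovery tests shows the chain of estimators is correct and close to
unbiased under its own assumptions at the study's sample sizes — not that
those assumptions hold in a clinic. In particular the synthetic in vivo
study is cleaner than real transcutaneous data: at a 10% true difference
it usually reaches significance at n = 10 + 6, whereas the corresponding
real-world comparison was underpowered. The sample-size machinery exists
precisely to quantify that gap from whatever scores a study produces.

## Numerical choices and degenerate inputs

* Window endpoints are inclusive everywhere; the axis convention is
  values *at* stated wavenumbers.
* Trimming may leave a gapped axis; downstream operations treat it as a
  channel set, and integrals are trapezoidal on the retained channels.
* All-zero (or non-positive-in-window) spectra make normalisation fail
  loudly; a zero-derivative vector has entropy 0 by convention; two
  zero-variance groups with equal means give p = 1, with unequal means
  p = 0; equal group means make the required sample size infinite and
  raise an error.
* Problem sizes in the test suite: end-to-end recovery uses 10 + 10
  subjects × 15 spectra (excised) and 10 + 6 subjects × 10 measurement
  stacks of 60 accumulations (in vivo), each over 20 seeds at true
  differences of 0, 5.5 and 10% — the design sizes of the studies the
  package models.

## Known limitations

* The per-subject BTEM estimate carries ~5% relative uncertainty in its
  collagen content at the default in vivo conditions; propagated to a
  10 + 6-subject cohort difference this is ±2–3 percentage points per
  study, the dominant error term of the in vivo arm.
* Photon-migration physics (offset-dependent sampling depths) is reduced
  to a single soft-tissue weight per measurement.
* PCA on 16 per-subject spectra is fragile by construction; the in vivo
  model is fitted jointly on all subjects' estimates, as the study design
  it mirrors did.
* Only the bone component is extracted; full multi-component resolution
  (explicit skin and lipid spectra) is out of scope.
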