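---
title: "Methods: quantifying duplex chromogenic RNA-ISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying duplex chromogenic RNA-ISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Duplex chromogenic RNA in situ hybridization stains two transcripts on one
FFPE section: the target mRNA (here an *ERBB2*-like oncogene transcript) as
discrete dark-blue dots and a housekeeping transcript (*POLR2A*-like) as
fast-red dots, over a blue-purple hematoxylin counterstain. Because RNA
preservation varies widely between archival FFPE blocks, absolute dot
counts are not comparable between samples; the quantity of interest is the
ratio of target to housekeeping dot counts, averaged over several
representative fields per sample and restricted to epithelial tissue.

`duplexish` implements the full analysis path: chromogen separation, spot
detection, ratio aggregation with quality control, cohort statistics, and a
synthetic-data generator that stands in for slide images, which are not
publicly deposited for this assay class.

## Chromogen separation

Both chromogens and the counterstain overlap heavily in RGB. Two pixel-wise
transforms separate them.

**Tritanope simulation.** A tritanope (absent S-cone) colour-vision
simulation collapses the blue-yellow axis: the blue chromogen becomes a
dark teal clearly darker than the counterstain, while reds are essentially
untouched. We use the linear-sRGB-to-LMS matrix of Viénot, Brettel &
Mollon (1999) and replace the S response by its projection onto the plane
through the origin spanned by the D65 white axis and the LMS direction of
monochromatic 485 nm light — the tritan confusion anchor of Brettel et
al. (1997). Two widely copied alternatives were rejected after
measurement: the Fidaner/"Daltonize" tritan coefficients map fast red to
yellow (a real tritanope sees red as red), which destroys the red channel
downstream, and the Machado (2009) severity-1 matrix is not a projection,
so it violates idempotence by ~20 8-bit levels on saturated reds. The
matrix and plane are configurable via `tritanope_matrices()`.

Two numerical details make the operation exact: out-of-gamut projections
are desaturated toward the equal-luminance gray *within the projection
plane* (naive channel clipping leaves the plane), and pixels already on the
plane within the worst-case quantization perturbation pass through
unchanged. Together these give bit-exact idempotence and gray preservation
under 8-bit quantization; without the pass-through rule, quantization of
the green channel is amplified by the sRGB toe into ~10-level blue-channel
oscillation near the gamut floor.

**Channels.** The target channel is the relative luminance (linear-light
Rec. 709 weights) of the tritanope image: blue dots are local minima. The
housekeeping channel is CIELAB a* (D65, 2°) of the tritanope image: fast
red keeps a* ≈ +30 while counterstain sits near 0.

## Spot detection

Detection follows the undecimated B3-spline à-trous wavelet scheme
standard in microscopy spot detectors. Defaults: scale 2 only (dot radii
2–6 px at the generator's geometry), threshold `k` times the MAD-based
noise scale of the detail plane, 8-connected components filtered to areas
of 5–2000 px, centroid-in-ROI membership.

Three implementation choices matter and were validated by measurement:

* **k = 3, not 2.** On any noisy image ~2.3% of pixels exceed 2σ, and the
  à-trous smoothing correlates them into contiguous 10–30 px blobs
  indistinguishable from dots (~40–70 false components per blank 256×256
  frame). At 3σ — the conventional wavelet detection threshold — false
  components essentially vanish while recall is unchanged.
* **One-sided clipping.** The working channel is clipped at its ROI median
  before the transform (noise σ is estimated from the unclipped plane).
  Without this, the positive wavelet ring around *opposite-sign* blobs —
  blue dots are negative in the a* channel — is detected as spurious
  spots (measured precision 0.30 on the housekeeping channel; 1.0 with
  clipping).
* **Morphological closing of the significance mask.** A blob much larger
  than the detection scale (a dense dot cluster) produces a boundary ring
  of significant pixels; noise breaks the ring into arcs that would each
  count as a spot. A 3×3 closing reconnects them so one merged blob stays
  one component.

Touching dots merge into single components by design: no watershed
splitting is attempted, so dense clusters are counted *below* their true
dot number. This deliberately reproduces the undercount that the original
workflow showed on strongly expressing (3+) tissue.

## Ratio quantification and QC

Per image, the ratio is target count over housekeeping count (undefined,
not infinite, at zero housekeeping). Per sample, the ratio is the
arithmetic mean of per-image ratios over QC-passing images — the
"average of five representative fields" convention; the pooled-count
alternative is available behind `method = "pooled"`. The two agree exactly
when housekeeping counts are equal across images, which the tests check.

The study excluded samples whose red channel failed (RNA degradation) or
showed diffuse fast-red background (endogenous alkaline phosphatase),
without numeric rules. We operationalize: `red_failure` when an image
yields fewer than 5 housekeeping dots; `red_high_background` when more
than 25% of ROI pixels exceed a* = 10 (diffuse redness rather than
discrete dots); a sample needs 3 of its nominal 5 images unflagged to
survive. All three thresholds are `quant_config()` keys.

## Synthetic data

The generator emulates the statistical structure the analysis assumes, not
histology. One field of view is a textured counterstain with an elliptical
epithelial ROI and paler stroma, anti-aliased circular dots of the two
chromogen colours (housekeeping dots also in stroma, at half density,
since the reference transcript is tissue-wide), optional tight clusters of
target dots, and optional diffuse fast-red haze. The counterstain mottle
and the epithelium/stroma transition are deliberately smooth (below the
detection scales): counterstain texture at 400× varies over tens of
pixels, and a generator whose background defeated the detector at its own
defaults would contradict the observation that the published workflow
detected dots reliably.

Default chromogen colours are dark blue-teal (60, 90, 110) for the target
and light pink (240, 120, 140) for fast red over counterstain
(160, 140, 190). The light fast red matters: its tritanope-filtered
luminance matches the counterstain (0.344 vs 0.303), so red dots do not
cross-fire in the dark target channel — the same property that lets the
real assay count blue dots in dark-spot mode. A dark crimson default was
measured to leak ~13 red dots per field into the target channel and was
rejected.

Cohorts: each sample draws a true ratio from Normal(group mean, group SD)
truncated below at 0.1 (the study's observed minimum was 1.521; the floor
only guards degenerate draws); each image draws a housekeeping count from
Poisson(25 by default) and a target count from Poisson(ratio × count), so
per-image ratios scatter around the sample ratio — the study reports no
within-sample dispersion, so this Poisson model is a stand-in. Default
group parameters are the published per-IHC-score summaries (2.51 ± 0.52
n = 20, 3.00 ± 0.50 n = 24, 3.81 ± 0.62 n = 18). Clinical covariates
(diagnosis, grade, invasion) are drawn at the published marginal
frequencies so the contingency layer has realistic inputs. A
`failure_rate` fraction of samples get collapsed housekeeping counts
(count mode) or maximal haze (image mode), exercising the QC path.

What a green test does **not** establish: the generator has no nuclear
morphology, no learned texture, no chromatic aberration or uneven
illumination, and its within-sample dispersion model is invented. Green
acceptance tests mean the pipeline recovers the truth of *this* stated
world; they are silent about stain variation in real archives.

## Statistics

All tests are implemented from first principles (and checked against
independent oracles in the tests): tie-corrected Kruskal-Wallis with
chi-square p (k−1 df; H = 0, p = 1 when all observations tie); two-sided
Mann-Whitney U, exact by dynamic programming over the null U distribution
for n₁+n₂ ≤ 20 without ties (p = 2·min(P(U≤u), P(U≥u)) capped at 1),
otherwise normal approximation with tie-corrected variance and 0.5
continuity correction; pairwise Mann-Whitney with Bonferroni
(min(1, m·p)) as the post-hoc — the study says only "post-hoc with
Bonferroni correction", and pairwise Mann-Whitney is the common reading;
Dunn's test was considered and not implemented to keep one documented
path. Exact contingency tests use the probability-ordering two-sided rule
(sum of margin-fixed table probabilities ≤ observed × (1 + 1e-7)): direct
hypergeometric enumeration for 2×2, complete recursive enumeration with
multivariate hypergeometric probabilities for r×c (bounded at 10⁷ tables,
with a seeded Monte-Carlo fallback via margin-fixed sampling). The
probability-ordering convention reproduces the published table p values
(0.395, 0.697, 0.317) exactly to 3 decimals, which adjudicates the
convention question.

One stated property was adjusted after analysis: distributional recovery
of cohort moments is tested at n = 20 000 per group rather than 500,
because the relative standard error of a sample SD at n = 500 is
1/√(2n) ≈ 3.2% — larger than the 2% band being tested, so a correct
generator fails for typical seeds. At n = 20 000 the band is ≈ 4 standard
errors.

## Limitations

* Single-plane tritanopia; the two half-plane Brettel variant would treat
  colours on the 660 nm side slightly differently. Matrices are pluggable.
* No dot splitting: counts saturate under heavy clustering (by design,
  matching the assay's reported behaviour, but a limitation for absolute
  quantification).
* Detection scale fixed at 2 by default; dots far from 2–6 px radius need
  `scales` adjusted.
* The exact r×c test is enumeration-bound; large sparse tables fall back
  to Monte Carlo.
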