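---
title: "Mapping fractional cover change in grasslands by constrained spectral unmixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fractional cover change in grasslands by constrained spectral unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassunmix)
```

## The problem and the model

Semi-arid grasslands are mosaics of grasses, forbs and exposed soil at
scales well below the pixel size of airborne imagery, so hard per-pixel
classification discards most of the signal. The linear mixing model (LMM)
instead treats each pixel's reflectance spectrum $r \in \mathbb{R}^B$ as a
convex combination of $K$ class *endmember* spectra $R_1,\dots,R_K$:

$$ r = \sum_{i=1}^{K} a_i R_i + \varepsilon, \qquad
   a_i \ge 0, \quad \sum_i a_i = 1, $$

where the weights $a_i$ are the sub-pixel *fractional abundances*.
`grassunmix` estimates them per pixel by fully constrained least squares
(FCLS): minimize $\lVert r - \sum_i a_i R_i \rVert^2$ over the unit
simplex. Downstream, the package turns two years of abundance maps into
per-pixel change slopes, histogram and area summaries, threshold-based
accuracy assessments at reference points, and paired nonparametric change
tests.

A seeded synthetic scene generator emulating a 1 m, 426-band (5 nm grid)
airborne acquisition supplies ground truth, so every stage is testable
end to end with no data download.

## The FCLS solver

The solver is an active-set non-negative least-squares (Lawson–Hanson)
iteration on the normal equations, with the sum-to-one constraint imposed
through a heavily weighted augmentation row. Two numerical details matter:

* **Augmentation weight.** The squared weight is $10^6 \cdot
  \max(\mathrm{diag}\,R^\top R)$. Larger weights pin the constraint harder
  but leak cancellation noise (of order weight $\times$ machine epsilon)
  into the gradient used for active-set entry; smaller weights let the
  constraint drift. With the chosen weight the entry tolerance
  ($10^{-8}$ of the data Gram diagonal) sits safely above the noise floor
  while still admitting classes with true fractions down to $\sim 10^{-6}$.
* **Exact polish.** After the active set converges, the solution is
  recomputed on its support by an equality-constrained (KKT) solve, so the
  returned fractions satisfy $\sum_i a_i = 1$ to machine precision. A final
  clamp absorbs only floating-point dust ($\le 10^{-9}$); it never hides a
  real constraint violation, and `unmix_cube()` reports a violation count.

Degenerate libraries (near-collinear endmembers, singular-value ratio below
$10^{-10}$ on the spectra matrix itself) fail loudly, naming the offending
class pair, rather than returning an arbitrary split. The other constraint
modes (`ols`, `sto`, `nnls`) share the same design pieces; the
unconstrained optimum also provides the lower bound used in the
residual-monotonicity test. An exhaustive simplex-lattice search
(`brute_force_unmix()`, guarded to $K \le 4$) is shipped purely as an
independent oracle: on seeded pixels the active-set solution agrees with
the lattice optimum to within the lattice step.

## What the synthetic scenes emulate — and what they do not

`simulate_scene()` draws a ground-truth fraction field, renders it through
the LMM, and injects the defects the preprocessing stage exists to catch.

* **Fraction fields.** Per-pixel Dirichlet draws with concentration well
  below one (defaults around 0.10–0.15 per class) produce the U-shaped
  abundance marginals seen in real semi-arid cover maps — heavy mass at
  low abundance plus a tail of nearly pure pixels, with a minority
  genuinely mixed. A small
  isotropic Gaussian smoothing (sigma 0.5 px by default) adds spatial
  coherence; each pixel is renormalized afterwards so simplex membership is
  exact. Heavier smoothing would look more like contiguous vegetation
  patches but destroys the pure pixels that reference-point digitization
  and ROI-based endmember extraction rely on; the default deliberately
  keeps both.
* **Spectra.** Endmember shapes are smooth parametric curves: vegetation
  classes carry a green peak, red absorption, a logistic red edge and
  liquid-water dips; the soil class is a concave monotone brightening
  curve. A seeded smooth perturbation separates repeated classes. The two
  vegetation classes are parameterized far enough apart (about 0.1 rad
  spectral angle) that the generator's own separability floor (0.05 rad,
  checked with an error) is never at risk under perturbation.
* **Defects.** The water-absorption windows (default band ranges 192–212
  and 282–314, 1-based inclusive) are overwritten with high-variance noise;
  a seeded pixel set is written as the no-data sentinel (−9999 in
  scaled-integer storage, scale factor 10,000).
* **Noise.** Within-class spectral variability is modeled as i.i.d.
  Gaussian noise per band — a package choice, since no quantitative
  variability model is available for the emulated acquisitions. Real
  spectra have correlated, abundance-dependent variability, directional
  (BRDF) effects and flightline seams; none of these are simulated, so a
  passing recovery test demonstrates correctness of the estimator, not
  field-level accuracy.

All randomness flows from one integer seed through a scoped generator
(`withr::with_seed`), so identical inputs give bitwise-identical scenes.

## Preprocessing rules and their order

`exclude_bands()` masks (never deletes) band ranges; `mask_invalid()`
flags pixels carrying the sentinel or any reflectance below `min_valid`
(default 0, so strictly negative reflectance invalidates a pixel);
`clip_to_polygon()` applies pixel-center containment. Two conventions are
worth stating:

* **Order.** `mask_invalid()` inspects only currently valid bands. Run
  `exclude_bands()` first: corrupted water-window bands contain negative
  values in most pixels, and masking on them would condemn the whole
  scene. The two pixel-level masks (invalid-data and clip) commute and are
  idempotent; band exclusion composes as the union of ranges.
* **Indexing and geometry.** Band ranges are 1-based inclusive at the
  configuration surface. Map coordinates are x-east/y-north with pixel
  (1,1) at the north-west corner; a point on a shared cell edge belongs to
  the cell to its south-east (half-open intervals). With the default
  ranges, 54 of 426 bands are excluded, leaving 372 — the package computes
  this arithmetic rather than hard-coding any expected remainder.

## Trend, summaries, thresholds

* **Slope.** For two acquisitions the per-pixel least-squares trend is
  exactly the difference quotient $(f_{t_2}-f_{t_1})/(t_2-t_1)$ in fraction
  units per year. The calendar-year difference (2022 − 2018 = 4) is the
  denominator convention: it makes the attainable slope range exactly
  ±0.25 per year, matching the customary legend bounds for such maps.
* **Categories.** All interval assignments in the package — trend classes
  (default breaks −0.085, −0.036, 0.037, giving decline / moderate decline
  / stable / increase), abundance classes (low/medium/high at 0.3 and
  0.6), and histogram bins — are lower-inclusive, with the last histogram
  bin closed at 1. The three published-style trend intervals leave a gap
  around zero; the default break set closes it by classifying the gap as
  part of the stable range, and breaks are fully user-configurable.
* **Medians.** Summary tables in this field sometimes conflate the median
  of pixel fractions with the median of the ten per-bin tallies.
  `histogram_counts()` reports both under unambiguous names, and
  `median_of_counts()` rounds half-integers away from zero only when
  integer output is requested.
* **Areas.** Abundance-weighted area is $\sum a \cdot$ pixel area / 10^4
  ha. For sum-to-one stacks the class areas add up exactly to the valid
  footprint area; this conservation law is asserted on every test scene.
* **Accuracy.** A reference point is predicted as the class whose fraction
  meets the threshold (largest wins, lexicographic tie-break; otherwise
  "unclassified", excluded from the matrix with a count). The bundled
  example tables follow the row/column convention of their source — user's
  accuracy computed along reference rows — which reverses the textbook
  assignment; `accuracy_metrics(convention = "standard")` swaps them.
  Metrics are returned unrounded.

## The change tests

The pairing unit is the abundance bin, not the pixel: differences of the
ten per-bin pixel counts between years feed both tests. The Wilcoxon
signed-rank statistic V (sum of positive-difference ranks, zeros dropped)
gets an exact two-sided p-value from the full sign-flip null distribution,
computed by convolution over the ranks and doubled on the smaller tail,
whenever the non-zero differences are tie-free and $n \le 25$; otherwise a
tie-corrected normal approximation with continuity correction is used and
flagged. The convolution is cross-checked in the test suite against full
$2^{10}$ enumeration at $n = 10$ and against the reference implementation
in base R. Shapiro–Wilk normality testing delegates to base R's
implementation of Royston's approximation, wrapped with the package's
error contracts; Q–Q points use Blom-type plotting positions
$(i - 0.375)/(n + 0.25)$ at every $n$.

Running the bundled example bin counts through this machinery:

```{r stats}
change_test_table(example_bin_counts())
```

## Configuration and orchestration

`run_pipeline()` executes simulate → preprocess → endmembers → unmix →
trend → summarize → validate → stats from one declarative YAML
configuration (strict keys by default; every violation is reported with
its key path). YAML was chosen as the configuration carrier because it is
the structured format the surrounding R toolchain parses natively. The
endmember stage extracts class mean spectra from high-purity regions of
the most recent year by default, mirroring ROI-based endmember practice;
`endmembers: {source: truth}` bypasses extraction for calibration
experiments. Every written artifact is listed with an MD5 content hash in
`manifest.json`, and a fixed config + seed reproduces identical hashes.
The default problem size — two 100 × 100 × 426 scenes — runs the whole
pipeline in a few seconds on one CPU; the test suite uses smaller scenes
(15–40 pixels a side, 30–120 bands) except where a contract is stated at
the 100 × 100 scale.

## Known limitations

* Only two acquisition dates: no multi-date regression or per-pixel
  significance testing.
* The linear model only: no nonlinear or multiple-endmember (MESMA)
  mixing.
* No reprojection, mosaicking, BRDF or topographic correction —
  reflectance is consumed as a finished Level-3-style product.
* GeoTIFF output is a plain multi-page TIFF with a JSON sidecar for
  wavelengths and georeferencing; it is not a georeferenced GeoTIFF in the
  GDAL sense.
* The bundled example accuracy table at the 75% threshold is internally
  inconsistent in its source (cells sum to 154 against a declared total of
  150); the package preserves it as printed and documents the discrepancy
  rather than repairing it.
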