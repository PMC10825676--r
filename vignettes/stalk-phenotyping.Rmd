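---
title: "Biomechanical stalk phenotyping: models, parameters and design choices"
author: "stalkmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical stalk phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stalkmech)
```

## The problem

Stalk lodging — the structural failure of a grain stem before harvest —
is a major yield loss in maize. Dissecting its genetic architecture
requires measuring the mechanical traits of individual plants at scale:
whole-plant bending strength and stiffness in the field, organ-level
geometry and rind resistance of each internode in the lab, and
tissue-level material properties of the rind itself. `stalkmech`
implements the computational half of such a phenotyping pipeline: it
turns raw instrument traces and image annotations into phenotypes, keeps
plant identity intact from field label to final table, and ships a
seeded synthetic-trace generator so that every analysis step can be
validated against known ground truth without any instrument.

## Plant identity

Each plant carries a QR label encoding a `StalkID` with the syntax
`LocationYear_Plot-Stalk` (e.g. `ID2021_101-3`). Because the ID becomes
a filename, characters that are illegal in filenames are rejected at
parse time. The QR payload repeats the ID three times, joined by a
double underscore; `correct_scanned_payload()` recovers the true ID from
any single misread character by per-character majority vote and reports
exactly which position of which copy was corrected.

Three design points deserve mention:

* **Delimiter.** A single underscore is legal *inside* an ID, so the
  joiner between copies must be distinct; the double underscore matches
  the printed payload pattern and is configurable.
* **Unequal copy lengths are fatal.** Insertion/deletion scan errors
  would require sequence alignment, and a wrong alignment silently
  fabricates an identity — the worst possible failure for a study keyed
  on plant identity. The function refuses instead.
* **No tiebreak.** When all three copies disagree at a position there is
  no safe majority; the payload is reported unrecoverable. A misread
  that happens to spell out the delimiter itself (an underscore read
  adjacent to a real one) is likewise unalignable; this is an inherent
  limitation of the encoding, not of the decoder.

## Field tests: cantilever model

The field device records force `F` at a load cell at height `h` and the
rotation `theta` of the stalk from vertical while the operator performs
three preload pushes to 5–10° and a fourth push to failure. The device
body stores the raw sensor angle (calibrated over 80–180°); the header's
vertical reference maps it to deflection angle, `theta = ref - raw`.
That mapping is explicit and configurable because raw device
coordinates are hardware-specific.

The mechanics are those of a tip-loaded cantilever under small-angle
assumptions:

* deflection: `delta = h * sin(theta)`
* bending strength: `M = max(F) * h` over the failure push
* flexural stiffness: `EI = phi * h^3 / 3`, with `phi` the slope of
  force versus deflection on the preload loading limbs

Units are strictly SI (N, m) inside this module; the relations above are
unit-coherent only in SI.

**Push segmentation.** The testing protocol defines *what* the pushes
are but not how to find them in a sampled record, so detection is an
explicit design choice: hysteresis thresholding on the deflection angle
(onset 2°, release 1°, both configurable). The failure push is the one
whose peak exceeds 15° or the push still in progress when the record
ends — stalks can fail below 15° so the end-of-file rule matters.

**Slope window.** "The linear portion" of the force–deflection curve is
likewise under-determined; the default fits the 20–80% force-quantile
band of each loading limb and reports R². The window is selected on a
smoothed copy of the force signal: selecting samples by their own noisy
values truncates the noise distribution at the band edges and
attenuates the fitted slope (we measured roughly a −4% bias at 2%
force noise before making this change; with smoothed selection the bias
is below 0.1%). The three per-cycle EI values are averaged
arithmetically and all are retained in the output.

## Rind puncture: keypoints A–D

A 2 mm probe is driven through the minor axis of an internode resting
on a platform, from 35 mm above the platform face to 5 mm below it, at
25.4 mm/s sampled at 1000 Hz. The force–displacement curve crosses four
characteristic points: initial contact with the proximal rind wall
(A), the mid-lumen force minimum (B), reengagement with the distal wall
(C), and the exit plane (D) where the probe tip is flush with the
platform. The phenotypes are identities on these keypoints: minor
diameter `D − A`, rind thickness `D − C`, rind penetration resistance
(the peak force), and an integrated puncture score (the trapezoidal
integral of force from A to D, with a pluggable weighting hook for
force–displacement-weighted variants; the unweighted integral is the
honest default since the published weighting lives elsewhere).

Detection choices, all configurable:

* **D is a fixture property, not a force feature.** The probe is zeroed
  on the platform face, so D is the known zero-plane displacement
  (default 0 in the instrument coordinate). It is reported exactly, not
  read off a sample.
* **Contact threshold** = pre-contact baseline median +
  `max(0.5 N, 5 × baseline noise s.d.)`, evaluated on a 21-sample
  centred moving average.
* **Reengagement threshold** is referenced to the mid-lumen trough
  level, not the free-air baseline: pith tissue keeps the mid-lumen
  force well above zero, so a baseline-referenced threshold would
  never be crossed downward on clean data. C is the *last* rising
  crossing before D, which makes the detector robust to spurious
  noise crossings inside the lumen.
* **Onset refinement.** A threshold crossing lags the true contact
  point by threshold/slope. Both A and C are therefore refined by
  fitting a line to the raw rising edge just past the crossing and
  extrapolating back to the local baseline; on clean data this removes
  the bias entirely, and on noisy data it keeps keypoint errors within
  about one sample spacing (0.0254 mm).
* **Blanks.** Damaged internodes are logged as empty instrument runs so
  file order preserves internode numbering. A trace whose peak force is
  strictly below 1 N is a blank: it gets NA phenotypes but keeps its
  row and its internode index.

Point B is named and reported but feeds no phenotype; no published
formula uses it. No correction is applied for the 5 mm over-travel
below the platform.

## Three-point bending

**Structural scale.** Dried whole stalks are loaded at the central node
and supported at the most apical and basal nodes; spans at least 10×
the stalk diameter preserve natural failure modes (shorter spans raise
a warning, never a silent rejection). For a load at distance `a` from
one support (`b` from the other, span `L = a + b`):

* moment profile: `M(x) = F b x / L` left of the load,
  `F a (L − x) / L` right of it
* strength: `M = F_max a b / L`
* stiffness: `EI = phi a^2 b^2 / (3 L)`, with `phi` fitted over
  crosshead deflections of at most 6 mm (small enough to leave no
  permanent damage); with `a = b = L/2` this reduces to the classical
  `phi L^3 / 48`.

Stalks that roll on the supports must be discarded, but rolling is a
judgement call made at the bench; the package only *flags* a candidate
(a force drop of more than 20% of the running maximum before 80% of
peak force) and leaves the discard decision to the operator.

**Tissue scale.** Rind strips (nominally 18 × 2.8 × 0.7 mm) are tested
over a 10 mm span: three preload cycles sweeping midspan strain between
0.3% and 1.4%, then loading to failure. Flexural stress is
`sigma = 3 F L / (2 w t^2)`; flexural strain is the classical midspan
relation `epsilon = 6 delta t / L^2`. The strain expression is
sometimes misprinted in the source literature with the strip width in
place of the span; only the span-based form is dimensionally consistent
and satisfies `E = sigma / epsilon` against beam theory, so it is the
form implemented. Young's modulus is the stress–strain slope over the
20–80% force band of the final loading limb (found from crosshead
direction reversals; a monotone trace warns and is analysed whole), and
failure stress/strain are read at peak force — whether first fracture
or peak force is the right event is unstated in the protocol, and peak
force is the reproducible choice.

This module works in instrument-native N and mm (so stresses come out
in MPa); only the field module is in N and m.

## Internode geometry from images

Stalks are photographed on a grid of known size (48 × 36 inches) with
the stalk base at the top of the image; a detector marks each node with
a normalized bounding box, one text file per image, named by StalkID.
The package consumes those annotations (it does not run or train the
detector): boxes are sorted by image y (ties broken by x), duplicate
detections (IoU > 0.5) are collapsed with a warning, and internode
lengths are Euclidean midpoint distances divided by the grid
calibration. Raw midpoint distance — not a projection onto the stalk
axis — is the published definition, so a curved stalk's lengths are
chord lengths. The calibration is pixel extent over physical extent; x
and y scales differing by more than 1% raise an anisotropy warning and
the mean is used. Internode 1 is the most basal interval, matching the
puncture module's indexing direction.

## Density and composition

Linear density of a sectioned internode is simply `m / L` (g/cm), with
a plausibility warning below a configurable mass floor. Forage fiber
assays report ADF, aNDF and lignin proportions; cellulose is
`ADF − lignin` and hemicellulose `aNDF − ADF`, so
`cellulose + hemicellulose + lignin = aNDF` holds identically and
ordering violations (`lignin ≤ ADF ≤ aNDF ≤ 1`) are rejected naming the
inverted pair. Proportions are accepted as fractions or percentages and
stored as fractions. Genotype-level pooling is a grouping key in the
output, not a computation.

## The synthetic generator

Every analysis is tested end to end against `simulate_*` functions that
invert the same mechanical relations from explicit ground truth:

```{r example}
gt <- stalk_ground_truth(EI_true_Nm2 = 25, strength_true_Nm = 15,
                         noise_frac = 0)
res <- analyze_darling(simulate_darling_test(gt, h = 0.7, seed = 1))
c(EI = res$flexural_stiffness_Nm2, M = res$bending_strength_Nm)
```

Default parameter ranges are what a maize biomechanist would call
typical of mature plants: stiffness 10–40 N m², strength 8–25 N m,
minor diameter 15–25 mm with a 1–3 mm rind, peak puncture forces
30–90 N, rind moduli 3–15 GPa, eight internodes of 8–18 cm. Force noise
is additive Gaussian with s.d. equal to 2% of peak force by default
(set `noise_frac = 0` for clean traces); the rotation and displacement
channels are clean, as crosshead position is servo-controlled. Each
simulator draws from a single seeded stream and records its seed in the
file header.

The generator emulates the *geometry* of real traces — push cycles,
wall bumps, pith plateau, failure-mode signatures (sharp drop for stalk
lodging, plateau-then-decline for root lodging, truncation without a
drop for bent-not-broken) — not real tissue mechanics: there is no
viscoelasticity, no plastic hysteresis in the preload cycles, no
multi-peak fracture, and wall force profiles are piecewise linear.
Passing recovery tests therefore demonstrates that the analysis
correctly inverts the stated mechanical models and is robust to
additive noise; it does not certify behaviour on pathological field
data, which is why every detector threshold is exposed and every
questionable trace is flagged rather than dropped.

## Numerical choices and problem sizes

* Fits are ordinary least squares (`stats::lm`); degenerate windows
  (fewer than 5 samples or zero span) are errors, not NA results.
* R² is computed directly from residuals so that numerically perfect
  synthetic fits do not trigger spurious warnings.
* Body numbers are written with 10 significant digits, which round-trip
  exactly through a double, making write → read → write byte-identical
  on the body — the round-trip tests rely on this.
* The test suite exercises 100 randomized stalks for noiseless recovery
  and 100 seeds at 2% noise; the acceptance script uses 25 stalks and
  50 seeds plus an exhaustive single-corruption barcode sweep. These
  sizes give stable means while keeping the default run fast.

## Known limitations

* The puncture keypoint detector assumes each rind wall lies in its own
  half of the A–D span; extremely thick-walled or hollow-free stems
  would need a different peak search.
* The integrated puncture score's published weighting function is not
  reproduced here; the hook accepts any user-supplied weighting.
* Field-device sensor calibration pairs are parsed and reported but not
  re-applied; the device is assumed to calibrate on board.
* The chronology audit flags out-of-order timestamps within a plot but
  never reassigns identities.
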