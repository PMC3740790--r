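---
title: "Why image similarity cannot validate registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why image similarity cannot validate registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regeval)
```

## The problem

Registration of a moving image $Z_M$ to a fixed image $Z_R$ seeks a
transformation $T(x,y) = (T_1(x,y), T_2(x,y))$ such that corresponding
content is brought into alignment. Its accuracy is the deviation
$\lVert T - T_\mathrm{true} \rVert$ from the true transformation. A common
shortcut is to score registrations by how similar the reformatted moving
image $Z_M(T(x,y))$ is to $Z_R$ — but similarity is maximized by *any*
transformation that rearranges intensities favorably, with or without
meaningful correspondence. `regeval` builds the smallest complete setting
in which this failure is provable: a synthetic scene with exact,
multi-valued ground truth, a null model (CURT) that maximizes similarity by
construction, and an evaluation that scores both similarity and
correspondence so their rankings can be compared.

## The synthetic scene and its ground truth

The fixed image is a bright disk ("ball") on a non-constant background.
The moving image is constructed by a copy-shift-paste edit: the top-left
rectangle of `region_width` $\times$ `region_height` pixels is copied,
shifted `shift` pixels to the right, and pasted over the existing content.
Within the top `region_height` rows this partitions the canvas into
(0-based column intervals):

| Region | Columns | Content | Admissible displacements |
|---|---|---|---|
| A | $[0, s)$ | duplicated (source band still present, copy also pasted) | $\{(0,0), (s,0)\}$ |
| B | $[s, w_r)$ | shifted content | $\{(s,0)\}$ |
| C | $[w_r, w_r+s)$ | pasted over, original content destroyed | $\emptyset$ (undefined) |
| D | elsewhere | unmoved | $\{(0,0)\}$ |

with $s$ = `shift`, $w_r$ = `region_width`. A displacement $u$ at fixed
pixel $(x,y)$ means the corresponding moving location is $(x+u_x, y+u_y)$,
x being the column index increasing rightward and y the row index
increasing downward. Intensity constancy
$Z_M(x+u_x, y+u_y) = Z_R(x,y)$ holds exactly for every admissible
displacement — the construction is geometric, so no noise is added by
default (`noise_sigma = 0`); the permutation-null identities below depend
on exact intensity conservation. `add_noise()` exists for robustness
experiments.

The region areas have closed forms used as test oracles:
$|A| = |C| = s \cdot h_r$, $|B| = (w_r - s)\, h_r$, with $h_r$ =
`region_height`.

**Defaults.** The canvas is 206 $\times$ 256 (width $\times$ height) with a
156 $\times$ 196 region shifted by 50 px, so the pasted copy lands flush in
the top-right corner; the disk has radius 36 px at $(103, 192)$ with peak
intensity 230 over a background in $[30, 130]$. The canvas size is our
choice (it is the smallest canvas on which that region/shift combination
reaches the right edge exactly); all dimensions are configurable. The
background is band-limited random texture (FFT-smoothed uniform noise,
$\sigma = 2.5$ px) — non-constant but with repeated intensity values, as in
any 8-bit photograph. A `"unique-ramp"` texture assigns every pixel a
distinct intensity (one level per pixel, hence an intensity range equal to
the pixel count) and is used where oracle tests need tie-free sorting. The
disk carries mild radial shading so it is not one large constant region.

What the generator does *not* emulate: real sensor noise, illumination
changes, multi-modal contrast, or smooth anatomical deformation. Passing
tests therefore show that similarity metrics can be gamed even under ideal
conditions — exact intensity constancy, single discontinuous edit — not
that the package models realistic image formation.

## CURT, the null model

CURT sorts the pixels of each image in order of increasing intensity and
maps the $k$-th smallest fixed pixel to the $k$-th smallest moving pixel.
By the rearrangement inequality this pairing minimizes the sum of squared
intensity differences over *all* $n!$ pairings (the test suite verifies
this against exhaustive enumeration on 6-pixel images), so CURT is the
best-case adversary for intensity-based similarity. When the moving image
is an exact permutation of the fixed image — as it nearly is under
copy-shift-paste — CURT's reformatted image reproduces the fixed image
bit-exactly: RRMS $= 0$, EID $= 0$, CC $= 1$.

Ties among equal intensities are broken by ascending linear (column-major)
pixel index in both images via a stable radix sort. The tie rule does not
affect any similarity value (tied pixels have identical intensities); fixing
it makes the permutation, and hence the displacement field and the
correspondence error, reproducible bit-for-bit.

CURT requires equal pixel counts and rejects mismatched pairs rather than
resampling. `permutation_to_field()` expresses the pairing in displacement
vocabulary; `reformat_by_field()` samples with nearest-neighbor rounding
(interpolation would break exact conservation) and clamps out-of-bounds
samples to the nearest edge pixel, reporting the clamped count. A periodic
boundary is available as an explicit option but is never a default: silent
wraparound produces exactly the kind of uninterpretable field this package
exists to expose.

## Similarity metrics

* **RRMS** $= \sqrt{\tfrac1n \sum_i (a_i - b_i)^2}$ — a metric on images
  (zero iff identical; the triangle inequality is property-tested).
* **CC** — Pearson correlation of paired intensities; errors on a constant
  image rather than returning a conventional value. Note the internal
  consistency this implies: RRMS $= 0$ forces CC $= 1$.
* **EID** — Shannon entropy (base 2, bits) of the normalized histogram of
  the difference image, one bin per integer difference value in
  $[-I_{\max}, I_{\max}]$. Zero iff the difference is constant; invariant
  to adding a constant to either image. The bin width (default 1, exact
  and parameter-free for integer images) and the logarithm base are config
  options for fractional-intensity data.

These are the standard definitions; they are isolated behind
`similarity_report()` so alternates can be swapped in.

## Correspondence evaluation

The pointwise error of an estimated displacement $\hat u$ against an
admissible set $U$ is $\min_{u \in U} \lVert \hat u - u \rVert_2$: a
multi-valued truth scores the best admissible match, because both mappings
of duplicated content are equally correct. Pixels with $U = \emptyset$
(region C) are excluded from every aggregate and counted separately — no
displacement can be "correct" about content that no longer exists.
Summaries report mean, median and max error plus the fraction of evaluated
pixels with error $\le$ a tolerance, 0.5 px by default (the sub-pixel
rounding bound), with per-region breakdowns. The Euclidean norm and the
mean/median/max aggregation are design choices of this package; the
correctness notion ("$T$ close to $T_\mathrm{true}$") does not prescribe
them.

The ground-truth **oracle** method picks one admissible displacement per
pixel — $(0,0)$ wherever admissible, $(s,0)$ in region B, and $(0,0)$ as a
placeholder in region C so the field remains applicable for reformatting
(C never enters the error aggregates).

## The dissociation report

Each method is ranked twice: by similarity (average of the per-metric ranks
of RRMS, $-$CC and EID; ties share the smallest rank) and by correspondence
(fraction-correct, mean error breaking ties). The verdict flags every
method whose two ranks disagree. On the default scene the expected picture
is:

* CURT wins all three similarity metrics — its reformatted image is near
  identical to the fixed image — while its fraction-correct is near zero;
* the identity alignment loses badly on similarity but is correct on
  regions A and D, i.e. $(|A|+|D|)/(|A|+|B|+|D|) \approx 0.516$ of the
  evaluated pixels at the defaults;
* the oracle has zero error everywhere evaluated, yet scores *worse*
  similarity than CURT because region C's content is unrecoverable.

That CURT outranks the error-free oracle on similarity is the sharpest form
of the argument.

## Numerical and design notes

* All generation is a pure function of the spec and seed; reruns are
  bit-identical, and the RNG state of the session is restored after use.
* Degenerate inputs: constant images error in CC; zero-size admissible sets
  return the excluded marker; strict config validation never substitutes
  defaults for unknown keys.
* Displacement fields serialize as two-page 32-bit float TIFF with the
  per-channel affine mapping into $[0,1]$ recorded in a JSON sidecar
  (round-trip exact to float32 precision); permutations as a two-column
  0-based row-major plain-text table; the truth as a label PNG plus JSON
  sidecar with the label-to-set table.
* Problem sizes in the test suite: exhaustive permutation oracles use
  3 $\times$ 2 images (720 pairings); entropy enumeration covers all
  $3^9$ difference images on 9 pixels; the dissociation property is
  checked on 100 seeded scenes at the full 206 $\times$ 256 default size.
  These sizes give exact oracles where exactness is the point and full-size
  realism where the claim is statistical.

## Limitations

The package demonstrates a negative result — similarity does not imply
correspondence — on one family of discontinuous, piecewise-constant ground
truths. It does not quantify how similarity relates to accuracy *within*
the capture range of a well-posed registration model, does not evaluate
landmark or overlap criteria, and does not model smooth deformations,
noise-dominated regimes, or multi-modal similarity measures.
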