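---
title: "Methods: digital volume correlation around a bone implant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital volume correlation around a bone implant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneDVC)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the analysis chain runs. The package
targets time-lapse micro-CT of trabecular bone around a metal screw
during in situ pullout: 25 µm voxels, a bright titanium screw (Ø 2.6 mm)
along the z axis, and displacement steps of the order of 0.1 mm at the
implant.

## The measurement model

Local DVC treats the reference scan `f` and the deformed scan `g` as two
noisy samplings of the same material configuration. Around each node of
a regular grid a cubic *subset* of gray values is extracted from `f` and
compared against `g` displaced by a trial offset; the image similarity
is the zero-normalised cross-correlation (ZNCC)

$$ c(\mathbf{d}) \;=\; \frac{\sum (f_i - \bar f)(g_{i+\mathbf d} - \bar g)}
   {\sqrt{\sum (f_i - \bar f)^2 \sum (g_{i+\mathbf d} - \bar g)^2}}, $$

summed over the voxels of the subset that are finite in *both* windows.
ZNCC is invariant to gain and offset changes of the gray scale, which is
what multi-scan acquisitions need. The displacement at the node is the
argmax of `c` over the integer search window plus a subvoxel correction.
Assumptions: the displacement is approximately constant over one subset
(translation-only matching — no subset rotation or stretch), and the
texture inside a subset carries enough gradient information to localise
the peak. Both hold for trabecular bone at subsets a few trabeculae
wide and the small per-step displacements of a stepwise protocol.

Masking is part of the model, not a preprocessing nicety: implant metal
correlates with its own streak artifacts rather than with bone motion,
and background/pore space carries no signal. Masked voxels are `NaN`
and never enter the sums; a node whose subset has fewer than
`min_valid_fraction` valid voxel pairs is flagged
`insufficient_valid`. The half-masked subsets at the interface remain
usable — exactly the region the experiments care about.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `node_spacing_vox` | 4 | voxels | map resolution; 4 × 25 µm = 100 µm maps |
| `subset_side_vox` | 17 | voxels | ~2 trabecular spacings; smaller subsets lose peak sharpness (see below) |
| `search_radius_vox` | 3 | voxels | ±75 µm, comfortably above the per-step motion between consecutive scans; raise it (e.g. 5) when tracking across a 100 µm step |
| `min_valid_fraction` | 0.5 | — | subsets at the screw surface keep working with half their voxels masked |
| `cc_min` | 0.5 | — | peaks below this are noise matches; flagged `low_cc` |
| smoothing radii | 4 / 1 | voxels / nodes | image median before morphometry; displacement median before strain |

## Subvoxel refinement and its bias

The integer optimum is refined by separable parabolic interpolation: on
each axis a parabola through the scores at offsets −1, 0, +1 puts the
vertex at \((c_{-1}-c_{+1}) / (2(c_{-1}-2c_0+c_{+1}))\), clamped to
(−0.5, 0.5); axes whose neighbours fall outside the search window, or
whose three scores are not concave, contribute no correction. Two
deliberate rules:

* **exact matches short-circuit refinement.** When the peak score is 1
  to machine precision the two windows are identical and the integer
  answer is exact; fitting a parabola through the (asymmetric)
  neighbours would manufacture a spurious fraction. This is what makes
  noise-free integer rigid motions come back with literally zero error.
* **separable, not full-quadratic.** A 27-point quadratic with cross
  terms would correct the coupling between axes, and gradient-based
  subset optimisation would do better still; both are out of scope as
  the package keeps the classic local-DVC formulation. The cost is a
  known *peak-locking* bias: the correlation surface is only locally
  parabolic, so subvoxel fractions are pulled toward integers — about
  10 % of the imposed gradient on the synthetic texture — and the bias
  grows sharply when subsets are small relative to the texture
  wavelength (broad, anisotropic peaks). This is why the default subset
  is 17 voxels and why the swap-symmetry property (ref/def exchange
  negates the field within 0.1 voxel) is only guaranteed at that scale.

Ties in the integer search are resolved deterministically: smallest
Euclidean offset norm first, then lexicographic (z, y, x). Node results
are independent, so any evaluation order gives bit-identical fields.

## From displacements to strain

The node grid doubles as a hexahedral mesh. After componentwise median
smoothing (radius 1 node, cubic 3×3×3 window — failed nodes are excluded
from the sample), the deformation gradient at each element centre comes
from trilinear shape-function derivatives, which at the centre reduce to
\( \partial u_a/\partial X_b = \sum_{\mathrm{corners}} s_b\, u_a /(4h) \)
with \(h\) the node spacing; displacements and spacing are both in
voxels, so **F** is dimensionless. From **F** = **I** + ∂**u**/∂**X**:
Green–Lagrange **E** = ½(**F**ᵀ**F** − **I**) (exactly zero under rigid
motion, and exactly the imposed tensor under any affine field — linear
fields are reproduced without discretisation error by trilinear
elements); volumetric strain det(**F**) − 1; and the maximum shear
scalar

$$ \gamma = \tfrac13\sqrt{2(\varepsilon_{xx}-\varepsilon_{yy})^2
  + 2(\varepsilon_{xx}-\varepsilon_{zz})^2
  + 2(\varepsilon_{yy}-\varepsilon_{zz})^2
  + 12\varepsilon_{yx}^2 + 12\varepsilon_{zx}^2
  + 12\varepsilon_{zy}^2}, $$

kept with these printed coefficients (the leading ⅓ and the factors 2
and 12); whether the classical octahedral-shear constant was intended
instead is left as found. γ ≥ 0 always, with equality exactly at
isotropic strain states. Strain is evaluated at one point per element
(the centre), matching a strain map at the DVC node resolution; elements
with any failed corner are flagged and carry `NaN`.

One boundary rule deserves its own sentence: the displacement median
filter leaves nodes whose window would be truncated by the grid edge
unchanged, because a truncated median is biased on smooth fields and
would break the affine-exactness property at boundary elements.

## Error quantification

Scanning the same unloaded sample twice and running the full chain
between the two scans measures the method, not the sample: the mean of
each displacement component over valid nodes is the *accuracy*
(systematic error) and its standard deviation the *precision* (random
error), converted to µm. For strain, the absolute values of all six
tensor components are pooled across valid elements into a single
accuracy/precision pair in µε, mirroring how such errors are reported
for this class of experiment. Standard deviations are population ones
(divide by *n*); at thousands of nodes the distinction from the *n*−1
convention is far below every tolerance used.

## What the synthetic phantom does and does not emulate

The generator thresholds a Gaussian random field (spectral construction,
periodic boundaries) at the quantile giving the target solid fraction —
BV/TV is therefore controllable to within counting noise — assigns
background/bone/screw gray levels, applies a 0.6-voxel Gaussian blur as
a stand-in for the scanner point-spread (subvoxel DVC needs gray-level
gradients at interfaces), and burns in a threaded cylinder along z
(sinusoidal radius profile, 200 µm deep threads at 400 µm pitch).
Defaults: BV/TV 0.32 and a 100 µm texture correlation length, a few
voxels at 25 µm — a free parameter chosen to resemble rodent trabecular
dimensions, not an anatomical claim.

Imposed warps resample by trilinear interpolation, pulling intensities
from \( \mathbf x - \mathbf u(\mathbf x) \) so that DVC tracking
reference → deformed recovers +**u**; voxels mapped from outside become
`NaN`, which exercises the masking path. Integer translations reduce to
exact index shifts. The pullout-envelope field carries the full axial
magnitude out to a plateau radius from the screw surface and cosine-tapers
to zero over a decay distance (defaults 400 µm each); its steepest-
gradient radius — surface + plateau + decay/2 — is the analytic location
of the induced shear shell.

Not emulated: beam hardening and metal streak artifacts, cortical bone,
anisotropic/plate-like trabecular architecture, scanner drift between
repeated scans. Passing tests on phantoms therefore validate the
*computation* (exactness, invariances, error propagation under additive
noise), not robustness to physics the phantom does not contain —
artifact-dominated voxels near a real implant degrade gracefully only
through the masking and `cc_min` paths.

Binary masks are transported through warps by interpolating the 0/1
field and re-thresholding at 0.5; boundary motions below half a voxel
therefore do not change the discrete mask (interpolation of a jagged
binary surface is effectively nearest-neighbour), which is why
volume-change checks are done on smooth-edged intensity objects.

## Degenerate inputs and other numerical choices

* IsoData threshold: intermeans fixed point iterated from the global
  mean, convergence at 0.5 gray levels; constant volumes are refused.
  The implant must be excluded (masked) before thresholding a
  three-phase volume, otherwise the fixed point lands between bone and
  metal instead of between background and bone.
* Screw axis alignment: principal component of the mask voxel cloud;
  refused when the first-to-second axis ratio is below 1.2. Order of
  operations is filter → align → threshold/mask.
* Zero-variance subsets (flat gray) have undefined ZNCC and are treated
  as invalid offsets.
* Stiffness fits use the loading envelope (new displacement maxima)
  outside stationary holds (|crosshead velocity| below 5 % of peak,
  which removes the relaxation pauses of stepwise protocols), over the
  20–80 % window of the preload-corrected force range; the window on
  the corrected range makes the slope invariant to a constant force
  offset. The break threshold for failure is a drop below 90 % of the
  running force maximum. The fit window and envelope handling are
  declared conventions — stepwise pullout reports rarely state theirs.
* Morphometry counts voxel centres inside the annular cylinder; partial
  ROIs are refused rather than silently clipped. Note the geometry this
  implies: the 0.5 mm shell around a 2.6 mm screw needs ≥ 3.7 mm of
  transverse field of view, i.e. more than a 128-voxel cube at 25 µm;
  calibration checks therefore use 160-voxel transverse extents.
* The config reader accepts a deliberately small TOML subset (sections,
  scalar and flat-array `key = value` lines) and rejects unknown keys
  outright; defaults equal the experiment settings above.
* Volume files: TIFF float32 carries data in [0, 1] and no NaN, so TIFF
  output is affinely rescaled with the inverse map and a NaN sentinel
  recorded in a JSON sidecar (round trip exact to float32); MetaImage
  (`.mhd` + `.raw`, doubles) round-trips bit-exactly and is the format
  used where exactness matters.

## Problem sizes used in the validation suite

The repeated-scan error protocol runs on a 128³ phantom (5 % additive
noise, the default DVC settings, ~19 700 nodes of which ~7 700 fall in
bone) — the full experiment at its native size. Engine-equivalence
checks against a brute-force correlator use ≤ 32³ volumes where
exhaustive enumeration is cheap; the envelope-recovery experiment uses a
64×128×128 phantom with a 0.8 mm screw and a ±5 voxel search window, the
smallest geometry that holds the complete displacement shell. These
sizes are the package's validation choices and are stated here so they
can be scaled up knowingly: DVC cost grows linearly in nodes × offsets ×
subset volume.

## Known limitations

Translation-only subsets bias displacements inside strong strain
gradients; peak-locking compresses small subvoxel gradients (see above);
median smoothing leaves grid-edge nodes unfiltered; the strain at an
element is a single-point evaluation, not a Gauss average; no multi-scale
search, no FE-regularised (global) DVC, no GPU path. The pullout-envelope
warp is a demonstration ground truth, not a mechanical model of interface
failure.
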