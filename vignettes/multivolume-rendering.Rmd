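---
title: "Multi-volume ray marching with a shared depth buffer"
author: "voxray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-volume ray marching with a shared depth buffer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxray)
```

## The problem

Direct volume rendering (DVR) produces images straight from a scalar
field: a ray is marched through the volume, every sample is classified
by a transfer function into color and opacity, and the contributions
are composited front to back. For surgical planning this is attractive
because the raw CT data stay authoritative — no segmentation-dependent
meshing, no loss of interior information — but planning also requires
*moving parts* of the scan independently: single vertebrae in a
scoliosis correction, a bone flap in a craniotomy, fragments of a
fracture. That turns one volume into many, possibly overlapping
volumes, and a naive per-volume renderer composited with plain alpha
blending gets occlusion wrong wherever the volumes' depth order varies
across the image.

The package implements the multi-pass answer: render the volumes one by
one, but share a per-pixel **hit-distance depth buffer** between the
passes. Each pass clamps its rays at the current depth and, on early
ray termination, writes its own hit distances back through a strict
less-than depth test. The occlusion error of the naive approach
disappears, at the cost of one well-understood limitation discussed
below.

## Scene model

A `scene()` is an ordered list of `volume_node()`s. Each node owns

* a `scalar_volume()` — intensities on a CT-like scale with per-axis
  voxel spacing (mm). Voxel centers sit at integer 0-based
  coordinates; the renderable local box is `[-0.5, dim-0.5] * spacing`
  per axis, so trilinear interpolation (with boundary clamping) is
  defined everywhere inside it;
* an optional 8-bit `segmentation_mask()` — one label in 0..255 per
  voxel, 0 meaning unassigned. Labels are looked up nearest-neighbor:
  they are categorical, and interpolating them would invent labels
  that exist nowhere in the mask;
* a `transfer_function()` — piecewise control points mapping intensity
  to RGBA, per-segment opacity multipliers (hiding a segment is
  multiplier 0; data are never modified), and a reference step;
* an `affine_pose()` mapping the node's local millimetre frame to
  world space, which is what makes nodes independently movable.

## Compositing and opacity correction

Samples accumulate front to back on premultiplied color,

$$C \leftarrow C + (1 - A)\,\alpha\,c, \qquad
  A \leftarrow A + (1 - A)\,\alpha,$$

with early termination once $A \ge \tau$ (default $\tau = 0.99$). The
stored transfer-function alphas are calibrated for a reference step
$s_\mathrm{ref}$ and rescaled to the actual step $s$ by the standard
exponential-transmittance relation

$$\alpha' = 1 - (1 - \alpha)^{s / s_\mathrm{ref}},$$

which keeps the accumulated opacity of a homogeneous slab invariant
under step refinement (the suite checks the closed form
$A_n = 1 - (1-\alpha')^n$ to $10^{-9}$). The transfer function is
evaluated piecewise-linearly between control points and clamped to the
end values outside their domain.

Transfer functions additionally support `interpolation = "constant"`
(left-constant step functions). This exists for a substantive reason:
a strictly increasing piecewise-linear transfer function always has a
ramp interval, and trilinear interpolation will land samples inside it,
producing fractional alphas. Fractional alphas make floating-point
compositing order-sensitive, so "binary opaque" scenes built from
linear transfer functions are binary only almost everywhere. A
left-constant threshold function (`tf_preset("bone_binary")`) is
*exactly* binary per sample, which is what lets the equivalence checks
below demand bit-identical output rather than output within a
tolerance.

## The multi-pass renderer

`render_scene()` initialises the frame buffer from the background, or
from a supplied opaque layer (color plus camera-space depth of
pre-rendered geometry, converted per pixel to ray distance), then for
every visible node in creation order:

1. `project_screen_rect()` — the node's eight box corners are projected
   into screen space; the pass only touches the pixels of the resulting
   rectangle (padded by one pixel, clipped to the viewport). A box
   entirely behind the near plane yields an empty rectangle and the
   pass is skipped; a box merely *crossing* the near plane falls back
   to the full viewport, a safe over-approximation for a case where
   the corner projection is undefined.
2. `render_volume_pass()` — per pixel, the ray is intersected with the
   node's local box (slab method), clamped at the frame buffer's depth,
   and marched. The pass output is composited over the existing color
   (`C <- C_pass + (1 - A_pass) C`), which is correct precisely because
   the clamp guarantees everything already in the buffer lies at or
   behind this pass's content along each ray.
3. `blit_depth()` — pass hit distances replace buffer depths where
   strictly smaller. Ties keep the earlier pass, matching the one-pass
   renderer's node-order compositing at a shared sample distance.

Depth is the Euclidean distance along the ray, not perspective z: all
passes share identical per-pixel rays, so per-ray distance makes the
clamp exact and the stored depth image resolution- and
far-plane-comparable.

### Sampling grids

By default a pass samples at segment midpoints
$t_\mathrm{enter} + (k + \tfrac12)s$, which halves the boundary bias of
endpoint sampling and is deterministic (no jitter). With
`align_global_grid = TRUE` samples sit at global multiples $k\,s$ of
the distance from the eye, so every pass — and the one-pass reference —
takes samples at exactly the same distances. The aligned grid is what
makes cross-renderer comparisons meaningful at bit precision; the
midpoint grid is the production default. The default step is half the
minimum voxel spacing in the scene.

## The one-pass reference renderer

`render_onepass()` marches each pixel once over `[near, far)` on the
global grid and, at every step, classifies the sample of *every*
volume containing the point, compositing contributions in node order
before advancing. It deliberately has no screen rectangles and no
skipping: it is the simple, slow ground truth.

For binary-opaque scenes with pairwise disjoint opaque voxel sets the
multi-pass renderer on the aligned grid reproduces it bit for bit, in
color and depth — the test suite asserts `identical()` on eight random
scenes of 2–8 overlapping-box volumes. The two renderers share their
per-sample primitives (ray generation, world-to-local transform,
trilinear lookup, classification) as single inline C++ functions, so a
sample taken at the same pixel and distance classifies identically in
both; what the comparison actually validates is everything built on
top: the per-volume pass structure, clamping, blitting, tie handling
and cross-pass compositing.

The same comparison documents the known limitation: two interpenetrating
*semi-transparent* volumes cannot be composited correctly volume by
volume, because sequential passes cannot interleave samples. The suite
constructs such a case and asserts the renderers *do* differ there,
and that non-interleaving semi-transparent scenes agree within the
residual transmittance bound $1 - \tau = 0.011$ left by early
termination.

## Acceleration structures, made invisible

Empty-space skipping (`build_skip_grid()`) partitions each volume into
cubic blocks (default edge 8 voxels) and stores per-block intensity
min/max over the block *dilated by one voxel*, so the trilinear support
of any sample inside the block is covered. At render time a block is
skipped only when the transfer function is provably zero over the
block's whole intensity range — evaluated exactly, since a piecewise
function attains its maximum on an interval at an endpoint or interior
control point — and the block contains no voxel of a currently hidden
segment (a conservative flag: per-block transparency is decided from
intensities alone, so re-showing a hidden segment can never turn a
skipped block visible). Skipped samples would have classified to zero
alpha, so skipping never changes a single bit of the image; the same
holds for disabling the screen rectangles. Both facts are asserted
bit-exactly by the suite, which is the point: acceleration must be an
implementation detail, not a quality trade-off.

## Segmentation and extraction

`paint_sphere()` assigns a label to every voxel whose world-space
center lies within a brush sphere, overwriting previous labels — a
scripted stand-in for interactive painting. `extract_segment()` then

1. computes the label's tight voxel AABB (`segment_aabb()`),
2. copies the AABB padded by 1 voxel (clamped at the source edges, so
   trilinear sampling near the segment boundary has support),
3. restricts the copied mask to the label and hides label 0 in the new
   node's transfer function, so the node shows the segment in
   isolation even though its box contains neighboring tissue,
4. composes the source pose with the AABB offset so the new node
   initially renders exactly in place, and
5. hides the label in the source via segment opacity 0.

Because the copied data are bit-identical and the pose offset is an
exact integer multiple of the spacing, the post-extraction in-place
render reproduces the pre-extraction image — the suite requires at
least 99 % identical pixels at 128×128 with any differences within one
pixel of the segment's projected silhouette, and in practice observes
exact equality on the keyhole phantom. Extracting all $k$ labels turns
a one-volume scene into $k + 1$ volumes (21 for the spine phantom's 20
segments, 2 for the keyhole, 6 for the 5-fragment fracture).

## Lighting

With `shading = TRUE` and a `point_light()`, samples are shaded
Lambert-style: the normal is the negated normalised central-difference
gradient (one-voxel epsilon, transformed to world space), the output
`base * (ambient + diffuse * max(0, n.l) * visibility)` with ambient
0.3 and diffuse 0.7 — conventional constants, configurable on the
light. Zero-gradient regions have no surface and are treated as fully
lit rather than black. `render_shadow_map()` runs the multi-pass
machinery depth-only from a camera at the light (a single perspective
light camera aimed at the scene center, frustum sized from the scene
bounds), and visibility tests compare distance-to-light against the
map plus a bias of two sampling steps, the usual guard against shadow
acne at this sampling density.

## The phantoms

`generate_phantom()` produces the three study datasets procedurally,
deterministically in a seed:

* **spine** (64×64×96): 19 ellipsoidal vertebra bodies with posterior
  protrusions along a laterally curved axis plus a shoulder-girdle
  bar — 20 labels; soft-tissue field 40 ± 10, bone 700 ± 30.
* **keyhole_skull** (64³): a spherical shell with a circular disk
  segment punched through its camera-facing side.
* **fracture** (64³): the shell partitioned into $k$ fragments by
  assigning each shell voxel to the nearest of $k$ seeded random
  directions — a spherical Voronoi partition, i.e. a partition by
  bisecting planes, chosen because it yields *exactly* $k$ connected
  fragments.

The two intensity modes are separated by hundreds of units, so the
bundled threshold-300 presets classify them cleanly and noise can
never cross the threshold (the suite checks soft < 250 < 450 < bone).
What the phantoms do **not** emulate: anatomical shape realism, partial
volume effects at real tissue interfaces, scanner artifacts, or
clinical voxel counts (the originals are 512×512×485–775; tests run at
desk scale, 64³–96³ and 128×128 images, which exercises every code
path at a fraction of the cost). Passing tests therefore validate the
renderer's geometry and compositing, not its behavior on any specific
patient anatomy.

`random_blob_scene()` builds the oracle-equivalence scenes: 2–8 small
volumes, each one bright ellipsoid (semi-axes ≤ 7 voxels), posed with
random rotations on a jittered 20 mm grid — bounding boxes overlap
while opaque voxel sets stay pairwise disjoint by construction (the
suite verifies the world-space separation). `overlapping_bars_scene()`
crosses two opaque bars, one tilted toward the camera, so each volume
is nearer on part of the image — the minimal scene where naive
blending must fail.

## Numerical choices and degenerate inputs

* Early termination threshold 0.99 and step = 0.5 × min spacing are
  defaults, not constraints; both are plain parameters.
* The aligned-grid sample index is computed as `ceil(t_enter / step)`
  with a one-ulp guard so the first sample never precedes the entry
  point.
* Out-of-range trilinear coordinates clamp to the boundary voxel;
  out-of-grid label lookups return 0 (unassigned).
* Depth ties between passes keep the earlier pass; combined with
  node-order compositing at shared sample distances in the one-pass
  renderer, tie pixels agree between the two.
* A ray clamped to `t <= near` marches nothing and returns fully
  transparent with no hit; a pass depth image is far-plane-valued
  where no hit occurred, making the min-blit a no-op there.
* Singular poses, non-increasing transfer-function control points,
  labels outside 0..255, and mask/volume dimension mismatches are
  rejected at construction time.

## Problem sizes

Tests render at 24²–128² over 28³–96³ voxel volumes; the acceptance
script uses 128×128 images throughout, eight equivalence scenes, and
full extraction of all three phantoms. On one CPU core the whole test
suite runs in well under a minute and the acceptance script in about
ten seconds — sizes chosen to exercise every pipeline stage (multiple
volumes, overlap, extraction, occlusion, acceleration structures) while
staying instant to iterate on.

## Known limitations

* Cross-volume translucency: sequential passes cannot interleave
  samples of different volumes, so heavily semi-transparent,
  spatially interleaved scenes render incorrectly by construction.
  This is inherent to the multi-pass design and is surfaced, not
  hidden, by the one-pass comparison.
* Labels are nearest-neighbor, so extracted-segment silhouettes are
  voxel-quantised; the one-voxel pad only guarantees intensity
  support, not sub-voxel label edges.
* The shadow pass uses a single perspective light camera; lights
  inside the scene bounds (which would need a cube map) are rejected.
* No foveated rendering, stereo, mesh rasterisation (an opaque layer
  is accepted as images instead), DICOM series reading, or 2D transfer
  functions.
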