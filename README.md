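# voxray

Multi-volume direct volume rendering with depth-buffer occlusion, as a
CPU R package.

Surgical-planning viewers need to show several independent volumes at
once — vertebrae separated for a spinal fusion, a bone flap lifted out
of a skull, the fragments of a fracture being re-aligned — each freely
movable, while still rendering straight from the CT intensities
(no meshing, no resampling). `voxray` implements the multi-pass
approach to this problem: every volume is ray-marched in its own pass,
and a shared per-pixel *hit-distance depth buffer* makes the passes
occlude each other correctly even where the volumes' bounding boxes
intersect. The package also implements the surrounding pipeline: ad hoc
8-bit segmentation (sphere brush), extraction of labeled segments into
new scene volumes, screen-space bounding-rectangle culling, min-max
empty-space skipping, gradient shading with a depth-only shadow-map
pass, a one-pass reference renderer used as the correctness oracle,
deterministic CT-style phantoms, NIfTI/NRRD/PNG/PFM input-output and a
command-line interface. The ray-marching kernels are C++ (Rcpp); the
scene model and everything else is plain R.

## The method

Per pixel, a ray is marched through one volume at sample spacing
`s` (mm), classifying each sample with the transfer function and
compositing front to back on premultiplied color:

    C <- C + (1 - A) * alpha * c        (color, premultiplied)
    A <- A + (1 - A) * alpha            (opacity)

where `alpha` is the step-corrected opacity
`1 - (1 - alpha_ref)^(s / s_ref)`. When `A` first reaches the early
termination threshold (default 0.99), the distance of that sample from
the eye is the ray's *hit distance*; rays that never reach it get the
far-plane distance.

The multi-volume renderer runs one such pass per volume (in creation
order), with two couplings through the frame buffer:

* each ray is **clamped** at the current per-pixel depth, so content
  already known to be in front of it truncates the march (`t < depth`);
* after the pass, its hit distances are **blitted** into the depth
  buffer with a strict less-than depth test, and the pass color is
  composited over the existing color.

A pre-rendered opaque layer (color + depth of rasterised geometry) can
seed the buffer, so meshes occlude volumes and vice versa. Per-volume
screen-space bounding rectangles (the projection of the volume's eight
box corners) restrict each pass to the pixels that can see it. The
approach is exact for opaque classifications; heavily semi-transparent,
spatially interleaved volumes are the documented limitation, and the
bundled one-pass reference renderer (`render_onepass()`, which samples
*every* volume at *every* step) both defines the ground truth and
exposes that limitation.

Segmentation is deliberately rough: an 8-bit label grid painted with a
sphere brush divides a volume into sub-volumes. `extract_segment()`
copies the label's padded voxel bounding box into a new volume node
posed so the segment renders exactly in place, and hides the label in
the source by setting its segment opacity to 0 — the voxel data are
never modified.

## Worked example

Extract the keyhole (craniotomy) segment of the skull phantom and lift
the bone flap 30 mm toward the camera:

```r
library(voxray)

ps <- phantom_scene("keyhole_skull", seed = 0, image_size = c(128, 128))
ps$scene
#> <voxray_scene> 1 node(s)
#>   [1] 'keyhole_skull' 64x64x64 +mask

sc <- extract_segment(ps$scene, 1L, label = 1L)
sc
#> <voxray_scene> 2 node(s)
#>   [1] 'keyhole_skull' 64x64x64 +mask
#>   [2] 'keyhole_skull_seg1' 16x8x16 +mask

sc$nodes[[2]]$pose <- pose_compose(pose_translation(c(0, -30, 0)),
                                   sc$nodes[[2]]$pose)
r <- render_scene(sc, ps$camera, render_params(), verbose = TRUE)
#> pass 'keyhole_skull': rect [0,128)x[0,128), 16384 pixels marched, 28.0% early-terminated
#> pass 'keyhole_skull_seg1': rect [6,65)x[65,125), 3540 pixels marched, 41.7% early-terminated
r
#> <voxray_render> 128 x 128 px, 33.1% covered, depth range [49.61, 384] mm

write_image(r, "keyhole.png", "keyhole.pfm")
```

The two passes show the screen-rect culling at work: the skull pass
covers the whole viewport, the small extracted flap only a 59 x 60
pixel rectangle. The depth range starts at 49.6 mm — the lifted flap,
now the nearest thing in the scene — and ends at the 384 mm far plane
(background pixels). `keyhole.pfm` holds exactly those per-pixel hit
distances.

The same pipeline is scriptable from a shell (see `inst/cli/voxray`):

```sh
voxray synth --kind keyhole --seed 0 --out-prefix kh
voxray render --scene scene.yaml --out img.png --depth img.pfm
voxray extract --volume kh_volume.nii.gz --mask kh_mask.nii.gz --label 1 --out-prefix flap
voxray compare img.png other.png --max-diff 0
```

## Conventions worth knowing

* Voxel centers sit at integer 0-based voxel coordinates; the
  renderable box of a volume is `[-0.5, dim-0.5] * spacing` per axis.
* Intensities are sampled trilinearly; labels nearest-neighbor.
* Depth means Euclidean distance along the ray from the eye (not
  camera-space z); opaque-layer z images are converted per pixel.
* File affines are used as given — no reorientation to a canonical
  axis convention on read.
* Pixel `(0, 0)` is the top-left pixel; rays pass through pixel
  centers.

See the vignette (`vignettes/multivolume-rendering.Rmd`) for the full
account of the model, parameter defaults, numerical choices and
limitations.
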