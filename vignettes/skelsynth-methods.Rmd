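---
title: "skelsynth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{skelsynth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelsynth)
```

`skelsynth` turns musculoskeletal kinematics into annotated synthetic images
for training human pose estimation models. This vignette explains the model
and the procedure, the parameters that matter (with units and defaults), the
numerical choices, and what the synthetic setup does and does not emulate.

## The skeletal model and forward kinematics

A `skeletal_model` is a tree of rigid body segments rooted at the pelvis,
which attaches to ground through a 6-DOF joint. Each joint carries an ordered
list of degrees of freedom, each bound to one *generalized coordinate*: a
rotation about a unit axis (radians) or a translation along one (meters).
Coordinates have hard ranges and defaults; the pose at the defaults (all
zeros in the bundled model) is the standing T-pose used as the rest pose for
mesh generation and rigging. The ground frame is right-handed, Y-up, meters.

Forward kinematics composes, per joint,

$$G_\text{child} = G_\text{parent}\cdot T(r_p)\cdot\prod_k D_k(q_k)\cdot T(-r_c),$$

where $T(\cdot)$ translates by the joint location in the parent/child frame
and $D_k$ is the k-th DOF transform; rotation DOFs compose intrinsically in
their listed order, matching the custom-joint convention of common gait
models. Joint centers are carried through the parent transform and checked
against the child-side computation to 1e-9; virtual markers are fixed offsets
in body frames.

Out-of-range pose values only warn by default (`strict = FALSE`), because
inverse-kinematics results in motion files routinely exceed model ranges by
fractions of a degree.

The bundled `demo_model()` has 14 bodies (pelvis, torso including the head,
and three segments per limb) with 29 coordinates and plausible adult segment
lengths and joint ranges. It exists so that the entire pipeline, including
tests and the acceptance experiment, runs without any external asset.

## Motion input and random poses

OpenSim `.mot` files are parsed with case-insensitive header keys, an
`inDegrees` flag that defaults to *yes* (the OpenSim convention), and tab or
multi-space delimiters. Degrees are converted to radians for rotational
columns; with a bound model the column's DOF kind decides, otherwise a name
heuristic (`_tx/_ty/_tz` suffixes mark translations) applies, and an explicit
override argument exists. To spread a fixed frame budget over several trials,
`extract_equal_frames()` gives each trial `floor(total/n)` frames (remainder
to the first trials) at evenly strided indices `round(k(F-1)/(q-1))` — so
every motion type is represented.

Random poses draw each coordinate independently from the uniform distribution
on its range. Root translations are held at their defaults by default
(`translation_policy = "fixed"`): the camera is sampled around the avatar
anyway, so randomizing global position would only move the subject without
adding pose variety. As with random-kinematics data generally, many sampled
poses are physically implausible (self-intersecting limbs); they are kept by
design, since range coverage is the point of the random subset.

## The procedural avatar

The avatar is one watertight capsule per body segment, merged into a single
mesh in the rest pose. Capsule axes are the segment bones; radii come from
per-segment presets (e.g. torso 0.14 m, thigh 0.07 m) scaled by
$1 + 0.15\,\beta$ with the morphology scalar $\beta \in [-2, 2]$, and the
`sex_tag` shifts shoulder/hip girth presets. The default target of 7,500
vertices (realized within ±20%) matches the vertex-count scale of statistical
body meshes, which matters because the bounding-box step experiment depends
on vertex density. Left-side capsules are exact mirrors of their right-side
counterparts and mid-line capsules use an even sector count with half-phase
azimuths, so a symmetric skeleton yields a sagittally symmetric mesh to
machine precision.

What the capsule avatar does *not* emulate: realistic skin geometry, soft
tissue, clothing wrinkles, face/hand detail, and textures. Annotations are
derived from the skeleton, not the mesh surface, so keypoint, depth and
kinematics labels are exact regardless; silhouettes, masks, bounding boxes
and visibility are only as anthropomorphic as a capsule body. Users with
better meshes can import them (`read_obj()`) and reuse the whole rigging and
annotation stack.

## Rigging, skinning and the control-bone construction

The armature has three bone kinds:

* **Segment bones** span each body's parent joint center to the next joint
  center along the chain. Leaf bodies (hands, feet) continue for a fixed
  0.12 m along a per-body direction (configurable in the model file; default
  the incoming chain direction). Branching bodies (pelvis, torso) take the
  midpoint of their distal joint centers — a deliberately short torso bone is
  avoided by the connector mechanism below.
* **Control bones** are fixed-length (0.10 m) parents of their segment bones,
  sharing the head and carrying the body's rest rotation. At pose time the
  body's simulated global transform change is applied to the control bone and
  the segment bone follows. The testable content of this construction is the
  identity $S_b = G_b(\text{pose})\,G_b(\text{rest})^{-1}$, which the test
  suite asserts to 1e-9 against a direct rigid-transform product.
* **Connector bones** are inserted wherever consecutive segment bones leave a
  gap above 1e-6 m. They participate in weight computation and their weights
  are then moved to the segment bone they originate from, which re-weights
  short branching bones (torso, pelvis) that would otherwise lose vertices
  near the armpit/hip to longer limb bones.

Skinning weights use an inverse-square point-to-segment distance law,
$w \propto 1/(d^2 + \varepsilon)$ with $\varepsilon = 10^{-6}\,\text{m}^2$,
truncated below $10^{-3}$ of the row maximum and renormalized to sum to one.
This is a deliberately simple stand-in for diffusion-based automatic weight
solvers: it preserves the properties the pipeline relies on (nearest-bone
dominance, partition of unity, connector transfer) without claiming to match
any particular solver bit for bit. Deformation is plain linear blend skinning;
candy-wrapper artifacts near twisting joints are inherited and accepted, as
is the absence of secondary soft-tissue motion.

The control-bone and leaf lengths are configuration values, not claims about
any reference implementation; they only set bone extents used by the distance
law.

## Camera model and annotations

The camera is an ideal pinhole with square pixels; the vertical FOV spans the
image height (default 1024 × 1024, so horizontal = vertical). Pixel
convention, stated explicitly because keypoint datasets depend on it: origin
at the top-left corner, `u` rightward, `v` downward, continuous coordinates.
Randomized cameras sit on a spherical shell around the avatar centroid
(radius 2.5–5 m, azimuth 0–360°, elevation −20–60°, look-at jitter ±0.1 m)
with FOV uniform on 30–120°. The shell parameters are package defaults chosen
to keep a standing adult fully or mostly in frame across the FOV range; the
FOV range itself is the documented generation condition.

Per frame, every joint center, body-frame origin and virtual marker is
annotated with:

* **pixel coordinates** — behind-camera landmarks are flagged, not dropped,
  so records stay rectangular;
* **depth** — the Euclidean camera–landmark distance in meters (not
  view-space z), so 2-D keypoints plus depth reconstruct 3-D positions;
* **visibility** — $1/(1+N)$, $N$ the number of per-segment convex collision
  shapes whose ray entry lies strictly before the landmark
  (within $10^{-9}$ of the ray length; a shape containing the camera counts
  at distance 0). Landmarks inside their own segment's shape therefore have
  visibility ≤ 0.5 by construction, and a ray grazing between two shapes can
  legitimately report no occluder. Collision shapes are convex hulls of each
  segment's assigned vertices, built once in body-local frames and moved
  rigidly — they do not follow skin deformation, and concave regions (the
  neck) are filled by convexity. Both effects are inherited limitations of
  engine-style convex colliders.
* **bounding box** — the axis-aligned 3-D box over every 25th vertex of the
  deformed mesh (stride configurable; index 1 always included), its 8 corners
  projected, min/max taken, then padded by 25 px per side. The box is not
  clipped to the image. The padding default follows the generation protocol's
  stated 25 px; where a 30 px padding is quoted for the published sample
  data, that is a downstream choice and remains configurable here.
* **kinematics labels** — the full generalized-coordinate vector.

## Rendering

A z-buffered software rasterizer (Rcpp) samples triangle coverage at pixel
centers with inclusive barycentric tests and interpolates inverse view depth
(which is perspective-correct for occlusion). RGB uses flat Lambertian
shading, $0.3 + 0.7\max(0, n\cdot l)$, over a solid, gradient or image
background, written as JPEG (quality 0.9). Masks are written as PNG: lossy
compression would corrupt labels. Silhouettes reuse the same rasterization,
so silhouette pixels are exactly the z-buffer hits. Segment masks hide
vertices whose weight to the segment's bone is below 0.5 (a vertex exactly at
the threshold is shown) and draw a triangle only when all three vertices are
shown; the alternative "any vertex" rule is available because per-triangle
behavior at mask boundaries is a genuine free choice — the all-vertices rule
makes masks conservative subsets of the silhouette. Faces with any vertex at
or behind the near plane (view z ≤ 1e-6 m) are culled rather than clipped;
with cameras on the sampling shell this never clips the avatar.

## Dataset pipeline and determinism

`plan_permutations()` expands a config into per-image records: poses cycle
over the extracted/seeded pose set, morphologies round-robin over the ten-way
default sweep (female/male × β ∈ {−2,−1,0,1,2}), and per-image camera and
appearance seeds are drawn once from the master seed. `generate_dataset()`
executes the plan into `images/`, `silhouettes/`, `segments/` and
`annotations/` with `annotations.csv` (wide schema: bbox, per-keypoint
u/v/depth/visibility quadruples, coordinates; 6 significant digits) and
`metadata.csv` (morphology, camera, seeds). The CSV column layout is this
package's own documented schema, versioned by a `# schema_version` header
line; the folder layout is the stable contract. Everything derives from the
master seed, so a config re-run is byte-identical in the CSVs and
pixel-identical before JPEG encoding — asserted end to end in the tests.

## Quality control

`bbox_step_experiment()` quantifies the cost of vertex subsampling: over
seeded random poses and cameras it reports $|\Delta\text{width}|$ and
$|\Delta\text{height}|$ of the unpadded box at strides 5–50 versus stride 1.
Differences are one-sided (the subsampled box can only shrink). We summarize
with the per-step and overall medians, which operationalizes "mostly below"
phrasing into a testable statistic; outliers (a fingertip or foot skipped at
an unlucky stride) are visible in the per-step maxima. On the bundled
avatar at defaults (100 images, 1024², ~7.5k vertices) the overall median is
about 5–6 px, within the 20 px budget the acceptance suite enforces.
`coordinate_distributions()` provides range-bounded histograms and per
coordinate Kolmogorov–Smirnov statistics against uniformity — random-pose
streams pass at $\alpha = 0.01$, $n = 10{,}000$, while real motion
concentrates mass around common postures. `keypoint_set_distance()` computes
per-name pixel distances between any two keypoint sets, the measurement half
of comparing external detector output against generated annotations (running
a detector is out of scope).

## Numerical choices and degenerate inputs

* Rotations via Rodrigues' formula; orthonormality asserted to 1e-9 in tests.
* Joint-center parent/child consistency checked at 1e-9 (skipped across
  translational DOFs, where the two sides differ by the translation).
* Convex hulls: incremental insertion with visibility tolerance
  $10^{-9}\times$ diameter; segments with fewer than 4 non-coplanar vertices
  are flagged degenerate and excluded from ray casting with a warning.
* Ray–hull entry via half-space clipping; the strictly-before rule uses
  $10^{-9}$ of the ray length, so a landmark exactly on a hull boundary does
  not count its own surface.
* Weight ties in vertex assignment break to the lowest bone index; zero-length
  capsule axes fall back to spheres; coincident joint centers trigger the
  leaf-bone rule with a warning.
* Test problem sizes (avatar resolutions of 600–3,000 vertices in unit tests,
  full 7,500 in the acceptance experiment; 32–64 px test renders vs 1024 px
  defaults) are chosen so the full suite exercises every path at the default
  conditions where the claims live, and scaled-down everywhere else.

## Known limitations

Single-person scenes only; no environment colliders, so visibility measures
self-occlusion. No lens distortion, depth of field, shadows, or global
illumination. The capsule avatar makes silhouette-dependent labels stylized;
mask and bounding-box statistics transfer to realistic meshes only
qualitatively. LBS has no pose-space correction. The `.mot` reader covers the
common text dialect, not binary storage formats, and inverse kinematics /
model scaling are explicitly out of scope: poses must already be generalized
coordinates.
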