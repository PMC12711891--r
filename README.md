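# skelsynth

Synthetic, automatically annotated training images for human pose estimation,
generated from musculoskeletal kinematics.

Markerless human pose estimation (HPE) models need large sets of images with
accurate keypoint labels. Manually annotated photographs are expensive and
their labels are only as good as the annotator's eye; motion-capture-driven
simulation can instead produce *perfect* labels for free, because the 3-D
position of every anatomical landmark is known exactly at every frame.
`skelsynth` implements that idea end to end as a self-contained R package:

1. **Skeletal model** — a simplified musculoskeletal (MSK) model: a tree of
   rigid body segments linked by joints whose degrees of freedom are bounded
   generalized coordinates *q* (joint angles in radians, pelvis translations
   in meters), plus virtual markers fixed in body frames. Forward kinematics
   composes the joint transforms down the tree,
   `G_child = G_parent · T(r_p) · Π_k D_k(q_k) · T(−r_c)`,
   yielding the global rigid transform of every body.
2. **Avatar** — a procedural, watertight, human-like capsule mesh generated in
   the rest (T-)pose around the skeleton (default ≈7,500 vertices), with a
   scalar morphology parameter β ∈ [−2, 2] scaling segment girth and a
   female/male preset.
3. **Rigging and skinning** — an armature of three bone kinds: *segment bones*
   spanning joint centers, fixed-length *control bones* carrying each body's
   rest rotation, and *connector bones* filling gaps between consecutive
   segment bones. Per-vertex skinning weights follow an inverse-square
   point-to-bone distance law; connector weights are folded back into their
   originating segment bone; the mesh deforms by linear blend skinning
   `v′ = Σ_b w_vb · S_b(v)` with `S_b = G_b(pose) · G_b(rest)⁻¹`.
4. **Annotation** — every frame gets: 2-D keypoints (pixel coordinates, top-left
   origin) for all joints, body origins and markers; Euclidean camera–landmark
   depth in meters; a visibility label `visibility = 1 / (1 + N)` where *N* is
   the number of rigid per-segment convex collision shapes the camera→landmark
   ray enters before the landmark; a padded 2-D bounding box of the (vertex
   subsampled) deformed mesh; and the generalized-coordinate values.
5. **Rendering** — a z-buffered software rasterizer produces 1024 × 1024 RGB
   images (JPEG), whole-body silhouettes and per-segment masks (PNG, selected
   by a skinning-weight threshold of 0.5).
6. **Pipeline & QC** — deterministic permutation of poses × cameras ×
   morphologies × appearance into the dataset layout
   (`images/`, `silhouettes/`, `segments/`, `annotations/annotations.csv`,
   `annotations/metadata.csv`), plus quality-control experiments for
   bounding-box step sensitivity and kinematics distributions.

Poses come either from OpenSim `.mot` motion files ("real" subsets) or from
uniform sampling within each coordinate's allowed range ("random" subsets).
Everything is generated procedurally — no mesh, texture or background assets
are required.

## Worked example

```r
library(skelsynth)

model <- demo_model()                 # bundled 14-body full-body model
#> <skeletal_model> skelsynth_demo: 14 bodies, 14 joints, 29 coordinates, 10 markers

avatar   <- generate_avatar(model)    # ~7,500-vertex T-pose capsule avatar
mesh_summary(avatar)$n_vertices
#> [1] 7550

armature <- build_armature(model)
#> <armature> 33 bones (connector: 5, control: 14, segment: 14)
weights  <- compute_weights(avatar, armature)

set.seed(1)
pose       <- random_pose(model)      # uniform within coordinate ranges
transforms <- forward_kinematics(model, pose)
deformed   <- deform_mesh(avatar, weights, skinning_transforms(armature, transforms))
cam        <- sample_camera(colMeans(deformed$vertices))
#> <camera> 1024x1024 px, fov 74.4 deg, at (0.28, 2.60, -2.99)

shapes <- build_collision_shapes(avatar, assign_vertices(weights, armature),
                                 rest_transforms(model))
ann <- annotate_frame(model, pose, deformed, cam, shapes, transforms)
head(ann$keypoints[, 1:6], 5)
#>                  name  kind        u        v    depth visibility
#> 1 joint_ground_pelvis joint 535.4816 486.2966 3.432248       0.50
#> 2        joint_lumbar joint 542.2996 491.8925 3.342567       0.50
#> 3         joint_hip_r joint 544.8768 472.4163 3.507238       0.50
#> 4        joint_knee_r joint 502.4782 498.1883 3.829728       0.50
#> 5       joint_ankle_r joint 479.6553 551.8940 4.090605       0.25
```

Each row is one landmark: `u`/`v` are pixel coordinates, `depth` the
camera–landmark distance in meters, and `visibility = 1/(1+N)` — the hip and
knee sit inside exactly one segment's collision shape (N = 1, visibility 0.5),
while the ray to the ankle crosses two further segments on the way
(N = 3, visibility 0.25). A full dataset is one call:

```r
cfg <- dataset_config("out_random", subset = "random", n_images = 100, seed = 42)
generate_dataset(cfg)
```

which writes JPEGs, silhouette and per-segment masks, and the two CSVs. The
command-line wrapper does the same from a shell
(`Rscript inst/cli/skelsynth.R generate --config cfg.yaml --seed 42 --out DIR`),
with `plan`, `qc-bbox-steps` and `qc-coord-dist` subcommands.

## Documentation

The methods vignette (`vignettes/skelsynth-methods.Rmd`) describes the
kinematic model, the rigging/skinning construction, the annotation
definitions, all tunable parameters with their defaults, and the known
limitations of the procedural avatar.
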