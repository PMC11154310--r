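# herd3d

Reconstructs a single 3D surface of a standing animal from a ring of
synchronized depth cameras — the capture setting of precision livestock
phenotyping, where body measurements are taken without handling the animal.
Two failure modes of real barns drive the design: the cameras vibrate, so
the calibrated extrinsics are only approximately valid at capture time, and
the pen's fences both occlude stripes of the body and contaminate the
frames with environment geometry.

The package implements the full chain in R (with C++ geometry kernels):

* depth-image ingestion: pinhole back-projection, pixel-grid triangulation,
  vertex normals;
* automatic segmentation of the animal: environment subtraction against a
  cached environment-only capture, removal of triangles with edges longer
  than twice the mesh mean (depth-discontinuity bridges), half-edge
  boundary-loop detection and erosion, small-component removal;
* sphere-target extrinsic calibration: the rig's pairwise center distances
  are mutually distinct, so sorted distance signatures identify
  correspondences and the camera-to-camera transform follows in closed
  form;
* the core contribution — interleaved multi-camera pose refinement
  minimizing

  $$E(T) = \sum_i \sum_{p \in P_i} \mathrm{Dist}(M, T_i\,p)^2 + \sum_i \Gamma(T_i, T_i^0),$$

  alternating between rebuilding the global surface $M$ from all cameras
  (Poisson-type reconstruction, depth 8) and per-camera Gauss–Newton
  alignment of the six pose parameters against $M$ (point-to-plane
  residuals, 0.14 m correspondence cutoff), with
  $\Gamma = k_r \sum r_j^2 + k_t \sum t_j^2$ anchoring each camera to its
  calibrated pose so that cameras cannot slide away along weakly
  constrained directions;
* final surfacing at depth 9, and a seeded population optimizer
  (elite-guided sampling over the ±3° / ±0.1 m calibration-error box with
  one camera fixed) as the global-search baseline;
* a synthetic scene simulator — parametric animal body, floor, fence bars,
  ray-cast depth rendering with per-pixel labels, pose perturbation and
  depth noise — providing ground truth for every stage.

## Worked example

```r
library(herd3d)

# a full synthetic study instance: 10-camera ring at 160 x 120, pose
# perturbations within +/-2 deg / +/-5 cm, 1 mm depth noise, fences
inst <- simulate_instance(seed = 1)
attr(inst$rig, "seg_stats")[1:3, ]          # per-camera segmentation tallies
#>   id animal_total animal_kept env_total env_kept
#> 1  0         4902        4632     10273        0
#> 2  1         4404        3961     11344        0
#> 3  2         5817        5426      8909        0

reg <- run_interleaved(inst$rig, verbose = TRUE)
#> [register] iteration 1: residual 10.882 mm
#> [register] iteration 2: residual 4.774 mm
#> ...
round(reg$trace, 2)                         # mean point-to-plane residual, mm
err <- pose_errors(reg$poses, rig_poses(inst$rig, "true"))
c(rot_deg = mean(err$rot_deg), trans_mm = 1000 * mean(err$trans_m))
mesh_stats(reg$mesh)                        # final depth-9 surface
```

The residual trace starts near 11 mm (the misalignment the perturbed
calibration leaves between the camera clouds) and drops to the
noise-and-discretization floor of one to two millimeters within about ten
iterations; the environment is removed completely while over 90% of the
animal surface survives segmentation. The gauge-aligned pose errors
plateau at the consensus-mesh bias floor discussed in the methods vignette
(`vignettes/herd3d-methods.Rmd`).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/herd3d.R simulate --seed 7 --width 160 --height 120 -o scene_dir
Rscript inst/cli/herd3d.R run --scene scene_dir -o out_dir
Rscript inst/cli/herd3d.R segment --frame f.ply --background env.ply --radius 0.02 -o cow.ply
```

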