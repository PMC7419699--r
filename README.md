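# boneDVC

Digital volume correlation (DVC) and peri-implant bone analysis for in
situ screw-pullout experiments under x-ray microtomography.

When a metal screw osseointegrated in trabecular bone is pulled out while
the sample is imaged at successive load steps, the pair of tomograms
around each step carries the full 3D deformation history of the
bone–implant interface. `boneDVC` implements the analysis chain that
turns such image pairs into mechanics:

* **local DVC** — cubic gray-value subsets around the nodes of a regular
  grid are tracked from the reference to the deformed volume by
  exhaustive search of the zero-normalised cross-correlation, with
  separable parabolic subvoxel refinement and NaN masking of the implant
  and background;
* **strain** — the displacement field is median-filtered and converted,
  element by element on trilinear (8-node isoparametric) hexahedra, into
  the Green–Lagrange tensor **E** = ½(**F**ᵀ**F** − **I**), the
  volumetric strain det(**F**) − 1, and the maximum shear strain
  γ = ⅓ √( 2(ε<sub>xx</sub>−ε<sub>yy</sub>)² + 2(ε<sub>xx</sub>−ε<sub>zz</sub>)² + 2(ε<sub>yy</sub>−ε<sub>zz</sub>)² + 12ε<sub>yx</sub>² + 12ε<sub>zx</sub>² + 12ε<sub>zy</sub>² );
* **error quantification** — accuracy (mean) and precision (standard
  deviation) of displacements and pooled |ε<sub>ij</sub>| from two
  repeated scans of an unmoved sample;
* **morphometry and geometry** — BV/TV in a cylindrical shell around the
  screw (IsoData binarisation), screw–plateau distance and tilt;
* **pullout mechanics** — stiffness, maximum force and failure detection
  from stepwise force–displacement records;
* **synthetic phantoms** — trabecular volumes (thresholded Gaussian
  random fields) with a threaded screw and analytic ground-truth warps
  (rigid, affine, pullout displacement envelope), so every stage is
  validated against known answers.

Default analysis settings are those of the targeted experiments: 25 µm
voxels, node spacing 4 voxels and 17-voxel subsets (a 100 µm DVC map),
median radii 4 (image) and 1 (displacement field), and a peri-screw ROI
extending 0.5 mm radially over a 2.2 mm span.

## Worked example

A 1.6 mm trabecular cube with a Ø 0.8 mm screw is dilated by 1 %
(**F** = 1.01 **I**, so det **F** − 1 = 0.0303) and corrupted with noise;
DVC and strain recover the imposed field:

```r
library(boneDVC)
spec <- phantom_spec(dims = c(64, 64, 64), screw_radius_um = 400, seed = 7)
ref  <- insert_screw(make_trabecular_volume(spec), spec)
def  <- add_noise(apply_warp(ref, warp_spec("affine",
                                            affine_matrix = diag(3) * 1.01)),
                  5, seed = 2)
masked_ref <- mask_phases(ref, 0, 170)$volume   # screw -> NaN
masked_def <- mask_phases(def, 0, 170)$volume
field <- run_dvc(masked_ref, masked_def, dvc_config())
summary(field)
#> DVC field: 1331 nodes, map spacing 100 um
#>                 ok             low_cc insufficient_valid      out_of_bounds
#>               1097                  0                234                  0
#> displacement over ok nodes:
#>   component  mean_vox sd_vox mean_um sd_um
#> 1       u_z -0.007398 0.1512 -0.1849 3.780
#> 2       u_y  0.006805 0.1778  0.1701 4.444
#> 3       u_x  0.006355 0.1799  0.1589 4.498
strain <- run_strain(field)
strain
#> <strain_field> 1000 elements (10 x 10 x 10), 674 valid
#>   vol strain: median 0.02262 [0.00327, 0.19660]
#>   max shear : median 0.00980, max 0.06121
```

The nodes inside the masked screw are flagged `insufficient_valid` and
never enter a correlation window. The median volumetric strain, 0.0226,
sits below the imposed 0.0303: parabolic peak interpolation compresses
subvoxel displacement gradients by roughly ten percent per axis at this
texture scale, a bias discussed in the methods vignette
(`vignettes/bone-dvc-methods.Rmd`).

`run_full()` chains phantom → masking → DVC → strain → error report →
morphometry from a plain-text config (see `parse_config()`), and
`inst/cli/bonedvc.R` exposes the same stages as shell subcommands.

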