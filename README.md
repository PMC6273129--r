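# chemfuse

Multivariate fusion of chemical images from paired vibrational
spectroscopic modalities — e.g. infrared absorption and Raman scattering
microscopy of the same sample area.

A chemical image cube is a 3-D array (rows x cols x bands) in which every
pixel holds a spectrum. Two modalities of the same sample see
complementary chemistry but rarely share a pixel grid: pixel sizes differ
(25 um vs 6.2 um in the default geometry — not a whole-number multiple),
and the fields of view are rotated, flipped and offset. `chemfuse` is for
spectroscopists and chemometricians who want to analyse such pairs
jointly. It provides:

* **Registration** of the high-resolution cube onto the low-resolution
  grid in five steps: per-cube PCA, Otsu thresholding of the selected
  score images into binary masks, orientation + antialiased bicubic
  down-sampling, affine optimisation by regular-step gradient descent on
  the mean square difference `MSD(F, M∘A) = mean((F - M(Ax))^2)`, and
  slice-wise application to every band.
* **Three fusion levels** with PLS-DA pixel classification: low
  (band-axis concatenation after autoscale -> block scale `1/sqrt(B_k)`
  -> maximum scale), mid (concatenated per-modality PC score images), and
  high (consensus of per-modality class maps, disagreement -> unknown).
* **Co-inertia analysis**: per component the dominant singular triplet of
  the concatenated centered blocks, with block-wise deflation on the
  global score and the block metrics
  `100 ||u_k||^2 / ||u||^2` (loading contribution),
  `100 cov^2(s_k, s) / Σ_k var(s_k)^2` (component contribution) and
  `cor(s_k, s)`.
* **Correlation maps** (Pearson r between every band pair across
  modalities, with >0.85 pairs reported as contiguous band ranges),
  **cross-modality PLSR** prediction with per-band relative-error spectra,
  and **resolution enhancement** (PLSR model trained at low resolution
  applied to the PCA-denoised high-resolution cube).
* A **phantom generator** producing paired cubes with shared latent
  concentration maps, known misalignment, class maps, noise and bad
  pixels — the ground truth behind every test.
* ENVI-style (header + binary) and CSV cube I/O, and a CLI
  (`exec/chemfuse`) wrapping the main workflows.

## Worked example

```r
library(chemfuse)

# paired phantom: IR-like 48x46 @ 25 um, Raman-like 185x194 @ 6.2 um,
# misaligned by a quarter turn, a flip and an affine jitter
ph <- make_phantom_pair(phantom_spec(seed = 2))
ph$a_lr
#> <chem_cube> IR: 48 x 46 pixels (25 x 25 um), 120 bands [wavenumber], 0 bad pixels
ph$b_hr_misaligned
#> <chem_cube> Raman: 185 x 194 pixels (6.2 x 6.2 um), 60 bands [raman_shift], 0 bad pixels

res <- register_cubes(ph$a_lr, ph$b_hr_misaligned, pc_low = 1, pc_high = 1,
                      rot90_quarter_turns = 1, flip_axes = "horizontal")
res$pipeline
#> <reg_pipeline> rot90 x1, flips [horizontal], target 48x46 (bicubic), final MSD 0.0036
b_reg <- res$registered

# classification at three fusion levels on the held-out image half
classify_cube(ph$a_lr, ph$truth$class_lr, max_lv = 8)$accuracy      # 100.0
classify_cube(b_reg,  ph$truth$class_lr, max_lv = 8)$accuracy      #  94.3
classify_cube(mid_level_fuse(ph$a_lr, b_reg),
              ph$truth$class_lr, max_lv = 8)$accuracy              #  94.3

# co-inertia block metrics
sc <- scale_blocks(list(unfold(ph$a_lr), unfold(b_reg)))
round(coinertia_metrics(coinertia_fit(sc$blocks, 2), c("IR", "Raman")), 3)
#>                                                            comp1   comp2
#> Contribution of IR loadings to global loadings (%)        74.895  71.449
#> Contribution of Raman loadings to global loadings (%)     25.105  28.551
#> Contribution of IR components to global components (%)   171.976 190.299
#> Contribution of Raman components to global components (%) 19.323  30.386
#> Correlation between IR block scores and global scores      0.995   0.999
#> Correlation between Raman block scores and global scores   0.956   0.995

# inter-modality band correlations and cross-modality prediction
cm <- correlation_map(unfold(ph$a_lr), unfold(b_reg))
nrow(high_correlation_pairs(cm, 0.85))                             # 787
m <- plsr_fit(unfold(ph$a_lr), unfold(b_reg), max_lv = 10)
median(m$test_r2)                                                  # 0.618
```

The registration pipeline (`final MSD 0.0036`) maps every Raman pixel onto
the IR grid; on this phantom the recovered transform agrees with the known
ground truth to under a third of a low-resolution pixel. The IR-only
classifier is perfect on pure pixels while the registered-Raman and fused
classifiers pay a small penalty for interpolation at class boundaries. The
component-1 block-global correlations (0.995, 0.956) say that the leading
co-inertia component is genuinely common to both modalities, as it must be
when both cubes image the same concentration maps. The median per-band
test R² of 0.618 for predicting registered Raman intensities from IR
spectra reflects residual interpolation noise; on ideally registered pairs
it exceeds 0.99 (see the tests).

End-to-end runs with a single declarative config:

```r
rep <- run_pipeline(run_config(input = list(preset = "phantom"),
                               stages = c("classify", "coinertia",
                                          "correlate", "predict", "enhance"),
                               seed = 4, out_dir = "out"))
writeLines(report_table(rep, "classification"))
```

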