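# atlascontour

Semi-automatic segmentation of brain MR structures by **multi-atlas
registration + active contour refinement**, for image-analysis researchers
and methods developers who need a fully inspectable, stage-by-stage
implementation with synthetic ground truth.

Manual delineation of structures such as white matter or the thalamus is
slow and subjective, and their boundaries are often low-contrast. This
package segments a target slice in four stages:

1. **Affine registration** — every atlas (an intensity image paired with an
   expert label image) is aligned to the target by a similarity transform
   `f'(p) = K R(θ)(p − c) + c + t`, maximizing the normalized
   cross-correlation (NCC) over the tissue bounding box; atlases with
   NCC > 0.87 are selected.
2. **Local weighted-voting fusion** — warped atlas labels vote per pixel,
   weighted by the 3×3-patch NCC between target and warped atlas intensity:
   `S(x) = argmax_c Σ_i w_i(x)·[M'_i(x) = c]`; thresholding the normalized
   score at 0.5 gives the binary *initial template*.
3. **Template optimization** — per-contour-pixel rectangular search areas
   (half-width 8, clipped to the midpoint between facing outlines) are
   scanned for true boundary pixels using the decision score
   `Y = w_p·P(x) + w_g·grad_norm(x)`, where `P` is a 20-bin intensity prior
   built from the atlas contour intensities and `grad_norm` the normalized
   Roberts gradient; accepted points (`Y ≥ 0.6`) are chained into the
   closed *initial active contour* (IAC), restoring small structures that
   consensus fusion loses.
4. **Snake evolution** — the IAC minimizes
   `E = ½∫ α|v′|² + β|v″|² ds + E_ext` with the hybrid potential
   `E_img = |grad_norm(G_σ∗I)² + P(x)|` (attraction toward high potential),
   by a semi-implicit scheme with a cyclic pentadiagonal solver, yielding
   the final smooth contour and its filled mask.

Evaluation (Dice, recall, precision, Hausdorff distance) and a synthetic
brain-like phantom generator with known ground truth are included, so the
whole pipeline is testable without any external data. The methods vignette
(`vignettes/methods.Rmd`) documents the model, every tunable parameter and
all numerical design decisions.

## Worked example

```r
library(atlascontour)

suite <- generate_phantom(phantom_config(seed = 1))   # target + 10 atlases
res <- segment_target(suite$target, suite$atlases,
                      pipeline_config("ibsr"), reference = suite$truth)

length(res$artifacts$registrations)   # atlases passing the 0.87 NCC cut
#> [1] 10
print(res$template_metrics)           # fused initial template vs truth
#> Dice 0.9699  Recall 0.9714  Precision 0.9684  HD 4.243 px
print(res$optimized_metrics)          # after template optimization
#> Dice 0.9891  Recall 0.9822  Precision 0.9961  HD 1.414 px
print(res$metrics)                    # final snake mask vs truth
#> Dice 0.9918  Recall 0.9838  Precision 1.0000  HD 1.000 px
length(unclass(res$artifacts$iac))    # main boundary + 2 satellite loops
#> [1] 3
```

The three metric lines show the method's mechanism: fusion gets close
(Dice 0.970 — it has lost the two small satellite structures and carries
residual registration error), template optimization recovers the satellites
and re-localizes the boundary (0.989), and the snake smooths the contour
(0.992, Hausdorff distance down from 4.2 px to 1 px). The recovered affine
parameters of each atlas are in
`res$artifacts$registrations[[i]]$params`; with anatomical inter-subject
variation switched off in the generator they match the stored ground-truth
transforms to within a degree and a fraction of a pixel.

Two parameter profiles ship with the package: `pipeline_config("ibsr")`
(white/gray-matter profile: `w_p = 0.7`, `w_g = 0.3`, snake 30/70/70) and
`pipeline_config("mrbrains")` (thalamus profile: `w_p = 0.6`, `w_g = 0.4`,
snake 60/100/100); `"custom"` accepts any override.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/atlascontour.R simulate --out suite_dir --seed 1
Rscript inst/cli/atlascontour.R segment --target suite_dir/target.fgm \
    --atlas-dir suite_dir/atlases --ref suite_dir/truth.pgm --out run_dir
Rscript inst/cli/atlascontour.R evaluate --seg run_dir/final_mask.pgm \
    --ref suite_dir/truth.pgm
```

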