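# cellstack3d

Recovering 3D cellular information from single acquisitions of
millimeter-scale **lensless fluorescence imagers**.

Chip-scale lensless imagers are small enough to be placed in a surgical
cavity for intraoperative tumor-margin assessment, but they trade away
optics: their point spread function (PSF) widens with the distance between a
fluorescent cell layer and the sensor, so a single acquisition of a tissue
stack is a sum of increasingly blurred layers. `cellstack3d` implements a
complete in-silico pipeline for extracting depth-resolved cellular maps from
such acquisitions:

1. **Phantom synthesis** — tumor-cell images are generated from lattice
   gradient (Perlin) noise: a coherent field is thresholded at 0.5 into a
   binary tumor mask of smooth cell foci, then filled with Gaussian signal
   and background intensities drawn from a configurable SNR range
   (51 × 51 pixels by default).
2. **Forward imaging model** — a depth-dependent PSF family
   `sigma(z) = sigma0 + slope * z` (flux-conserving Gaussian by default, or
   measured kernel banks) blurs each layer at its depth; multi-layer stacks
   are summed into the raw sensor view. An opposing **dual-sensor geometry**
   places a second imager across the 1 mm tissue stack, so a layer near one
   sensor is far from the other (effective depths always sum to the
   separation).
3. **Neural reconstruction** — four seeded convolutional networks, trained
   by a compact Adam/backprop engine written in RcppArmadillo:
   a depth classifier over 20 bins (50 µm – 1.95 mm, 100 µm steps), a
   6-layer conv/deconv deblurring network, a two-layer depth-map regressor
   and a four-layer per-pixel cell detector (single- or dual-sensor input;
   encoder-decoder or residual-trunk variants).
4. **Evaluation & 3D export** — per-pixel error rate, sensitivity,
   specificity, pooled ROC/AUC, depth accuracy and max error, and a voxel
   reconstruction (CSV + multi-page TIFF) that places the detected planes in
   the inter-sensor space.

## Worked example

Train and evaluate the dual-sensor four-layer detector at desk scale
(single CPU, a few minutes):

```r
library(cellstack3d)

cfg <- default_config(fast = TRUE)
report <- run_experiment("overlap_dual", cfg, seed = 1)
round(report$metrics$layer_error_rates, 3)
#> [1] 0.205 0.333 0.334 0.212
report$metrics$auc
#> [1] 0.8148585
```

The four numbers are mean per-pixel error rates for layers 1–4 (layer 1
closest to sensor A): with two opposing sensors the profile is symmetric —
outer layers are seen sharply by the near sensor, and the middle layers are
the hardest for both. The same run with `"overlap_single"` yields
`0.227 0.332 0.393 0.434`: a single sensor degrades monotonically with
depth, and the dual geometry cuts the far-layer error by half.

Individual stages are ordinary functions:

```r
img  <- generate_cell_image(seed = 42)          # phantom + mask
psf  <- psf_model(sigma0_px = 0.5, slope_px_per_mm = 4)
view <- blur(img, depth_um = 700, psf)          # one acquisition
plot_view(view)

stack <- layer_stack(lapply(1:4, generate_cell_image) ,
                     depths_um = c(100, 350, 600, 850))
viewA <- compose_stack(stack, psf, "A")         # raw dual-sensor pair
viewB <- compose_stack(stack, psf, "B")
```

Fitted models come with broom-style accessors (`tidy()` for the loss
history, `glance()` for a one-row summary) and `autoplot()` methods for
training curves and ROC curves.

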