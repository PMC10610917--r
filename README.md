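# pfseg — plantar foot segmentation for cold-stressed infrared thermography

Cold-stressed active thermography records a 10–15 minute sequence of
radiometric thermal frames while a patient's feet rewarm after cold
immersion. Early in the sequence the feet are colder than the ~22 °C
background, mid-recovery they pass through it (near-zero contrast), and
late in recovery they are much warmer — so no fixed threshold can segment
the feet across a whole sequence. `pfseg` is an R implementation of a
complete pipeline for this problem, aimed at researchers working with
plantar thermogram sequences (or methodologists studying segmentation
under contrast reversal):

* **Radiometric calibration** — two-point black-body calibration
  (`calibrate_two_point()`) and fixed temperature windowing
  (`temperature_to_grayscale()`), with automatic cropping of the
  calibration targets (`crop_calibration_targets()`).
* **Two-stage adaptive gamma transform** — per-image CDF statistics
  `x0` (median) and `x1` (upper quartile) give the contrast ratio
  `β = (x1 − x0)/x0`; frames with `β ≤ 1` (dark, early recovery) are
  brightened with `γ = 0.5 + x0` (or `1/(1.5 − x0)` above the median
  0.5), frames with `β > 1` with the reciprocal exponent; then
  `V_out = V_in^γ` (`enhance_two_stage()`).
* **PFSNet** — a U-shaped encoder–decoder segmentation network built from
  residual U-blocks (RSU-7…RSU-4 plus the dilated RSU-4F), nested dense
  skip connections, convolutional block attention (CBAM) at each fusion
  junction, and multi-side-output fusion producing 11 supervised sigmoid
  saliency maps (`new_pfsnet()`, `pfs_forward()`). The network engine —
  convolution, batch norm, pooling, bilinear resizing, attention, and
  reverse-mode differentiation — is implemented in the package (R + Rcpp).
* **Deep-supervision loss and metrics** — summed binary cross-entropy per
  output map with per-term weights (`bce()`, `total_loss()`); Dice, IoU,
  Hausdorff distance, histogram entropy, MSE, PSNR (`dsc()`, `iou()`,
  `hd()`, `entropy()`, `mse()`, `psnr()`).
* **Synthetic phantoms** — a seeded generator of cold-recovery sequences
  with ground-truth masks, black-body patches and NETD-scale sensor noise
  (`phantom_config()`, `simulate_recovery()`, `build_dataset()`), since no
  public dataset exists for this acquisition protocol.
* **Training and CLI** — SGD with momentum 0.9 and weight decay 1e-4
  (`train_config()`, `train_pfsnet()`, `segment_images()`), plus a thin
  command-line front end in `inst/cli/pfseg`
  (`synth | enhance | train | segment | evaluate | compare-enhancers`).

## Worked example

Generate a phantom sequence, window and enhance two frames — one early
(dark) and one late (high-contrast):

```r
library(pfseg)

cfg  <- phantom_config(width = 96, height = 80, frames = 600, seed = 7)
seqn <- simulate_recovery(cfg, c(11L, 591L))     # frames at t = 10 s, 590 s
win  <- phantom_window(cfg)
for (k in 1:2) {
  gray <- crop_calibration_targets(
    temperature_to_grayscale(seqn$frames[[k]], win), cfg$bb_regions)
  enh <- enhance_two_stage(gray)
  cat(sprintf("frame %3d:  x0 = %.3f  x1 = %.3f  beta = %.3f  gamma = %.3f\n",
              seqn$frame_indices[k], enh$params$x0, enh$params$x1,
              enh$params$beta, enh$params$gamma))
}
#> frame  11:  x0 = 0.398  x1 = 0.402  beta = 0.009  gamma = 0.898
#> frame 591:  x0 = 0.402  x1 = 0.996  beta = 1.479  gamma = 1.109
```

On the early frame the median and upper quartile nearly coincide
(`β = 0.009 ≤ 1`): the frame is classified dark and brightened (`γ < 1`).
On the late frame the warm feet pull the upper quartile to 0.996
(`β = 1.479 > 1`): the frame is high-contrast and compressed (`γ > 1`).

The end-to-end experiment — train a desk-scale PFSNet (width ×1/8, 64×64
input, batch 5, lr 0.05, 300 SGD steps) on ten enhanced phantom frames and
evaluate the dark early-stage frames of two held-out sequences:

```r
d <- demo_run(seed = 1)        # ~3 minutes on one CPU
round(c(train_dsc = d$train_dsc, dsc_enhanced = d$dsc_enhanced,
        dsc_unenhanced = d$dsc_unenhanced,
        entropy_original = d$entropy_original,
        entropy_enhanced = d$entropy_enhanced), 4)
#>        train_dsc     dsc_enhanced   dsc_unenhanced entropy_original
#>           0.9847           0.9592           0.9579           3.1536
#> entropy_enhanced
#>           3.1518
```

Training Dice reaches 0.98 on the ten training frames; on held-out dark
frames, segmenting through the enhancement path scores slightly higher
Dice than the raw path, and the enhancement lowers the mean histogram
entropy.

## Documentation

The methods vignette (`vignettes/pfseg-methods.Rmd`) describes the model
and its assumptions, the parameters that matter and their defaults, what
the phantom generator does and does not emulate, and the package's
numerical choices.
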