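# cobbnet

Computer-aided Cobb angle measurement for scoliosis assessment on
posteroanterior spinal radiographs.

Manual Cobb measurement — drawing lines along the endplates of the most
tilted (end-) vertebrae — varies by up to 5° for one reader and 7° between
readers, the same order as the 5° change that signals curve progression.
`cobbnet` replaces the line drawing with a regression network: the reader
only clicks the vertebrae of a curve, the network predicts each vertebra's
endplate slope from the 150×150-pixel patch at the click, and the Cobb
angle is computed automatically as

    Cobb = |s_upper| + |s_lower|,

where `s_upper` and `s_lower` are the largest predicted slopes tilting in
opposite directions.  The network is

    A(P) = b4 + W4 tanh(b3 + W3 tanh(b2 + W2 W1 (P − b1))),

a 2500-input regressor whose first layer is a fixed PCA projection (b1 =
mean patch, rows of W1 = first 100 covariance eigenvectors), followed by
two tanh hidden layers (500 and 50 units by default) initialized by
tied-weight autoencoder pretraining and fine-tuned by backpropagation.

Because no public data pairs radiographs with exact per-vertebra slopes,
the package includes a synthetic spine-phantom generator: 17 vertebrae
(T1–L5) on a smooth C- or S-shaped midline with maximum slopes in 5°–50°
(population mean |slope| 15°), rendered at the standard 1000-px height with
pedicle lead markers whose orientation encodes the exact ground-truth
slope.  Everything — training, evaluation, and a simulated-examiner
reliability study (ICC(2,1) with 95% CI, mean absolute difference) — runs
end to end on these phantoms.

## Worked example

Generate phantoms, train a small network, and measure a fresh radiograph:

```r
library(cobbnet)

# 30 training phantoms under the default study conditions
rgs <- lapply(1:30, function(s)
  render_radiograph(generate_spine_spec(seed = 1000 + s),
                    noise_level = 5, seed = s))

# 30 x 17 x 10 jittered, exactly-labeled training patches
patches <- sample_training_patches(rgs, patches_per_vertebra = 10,
                                   jitter_radius = 15, seed = 7)
model <- train_slope_dnn(patches, training_config(finetune_epochs = 30,
                                                  seed = 11))

# held-out phantoms: one centred patch per vertebra
test_rgs <- lapply(1:10, function(s)
  render_radiograph(generate_spine_spec(seed = 5000 + s),
                    noise_level = 5, seed = 100 + s))
test_patches <- sample_training_patches(test_rgs, 1, 0, seed = 8)
evaluate_slope_mae(model, test_patches)
#> [1] 0.7427303

# measure one radiograph from clicks at the 17 vertebra centres
v <- test_rgs[[1]]$truth$vertebrae
measure(test_rgs[[1]]$image, cbind(x = v$center_x, y = v$center_y), model)
#> Cobb angle: 102.0 deg
#>   end-vertebrae: clicks 2 (51.4 deg) and 16 (-50.6 deg) of 17
true_cobb_angle(test_rgs[[1]]$truth)
#> [1] 99.7263
```

The held-out mean absolute slope error is 0.74° with this deliberately
small training run; the measured Cobb angle of a severe synthetic curve
(102.0°) agrees with the generator's exact ground truth (99.7°) to about
2°.  A simulated repeat-measurement study quantifies reliability when the
only variability is where the examiner clicks:

```r
reliability_study(test_rgs, model, design = "intraobserver",
                  sessions = 2, click_noise_sd = 5, seed = 21)
#> intraobserver reliability (ICC(2,1)), 10 subjects x 2 sessions
#>   ICC = 0.997 (95% CI 0.988, 0.999), MAD = 1.79 deg
```

A command-line interface wrapping the same functions ships in
`inst/cli/cobbnet` (subcommands `generate`, `patches`, `train`,
`eval-slopes`, `measure`, `study`; see the file header for usage).

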