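# carfind

Label-free digital counting of CAR T-cells captured on a
CD19-functionalized microfluidic sensor surface and imaged by brightfield
microscopy.

## The problem

Monitoring CAR T-cell expansion in patients calls for counting engineered
T-cells directly in small whole-blood samples, without staining, flow
cytometry or operator-dependent gating. After red-blood-cell depletion and
surface capture on recombinant CD19, the captured cells are tiled across a
linear channel (203 µm × 1.0 mm × 35 mm, 7.1 µL) as 16-bit brightfield
images (6.5 µm camera pixel behind a 40× objective, 0.1625 µm/px at the
sample plane, 2048 × 2048 per tile, 30 tiles per scan). The residue on the
surface is messy: alongside lymphocyte-scale cells (7–15 µm) it holds
platelets, residual RBCs and debris, often crowded together. `carfind`
turns those tiles into a concentration in cells/µL.

## The method

**Candidate detection** is a five-stage prefilter, applied per tile:

1. *Local standard-deviation filter* — each pixel becomes the population
   SD of its w × w neighborhood, rectifying contrast polarity (defocused
   cells may be bright- or dark-centered).
2. *Match filter* — zero-mean normalized cross-correlation of the texture
   response with a rotationally symmetric annulus template; flat
   background scores 0, output in [−1, 1].
3. *Negative-value thresholding* — responses below max(0, t) are zeroed.
4. *Local-maxima identification* — greedy non-maximum suppression with a
   minimum peak separation.
5. *Radial segmentation* — rays cast from each peak over the original
   tile stop where the deviation from the local background falls below a
   fraction of its center value; the enclosed star-shaped mask, filtered
   by area bounds, defines the candidate. Crowded neighbors stay separate
   because each peak is segmented independently.

**Classification.** Each candidate yields a 16-feature vector (shape,
intensity statistics over the mask, ring contrast, texture, peak score)
fed to a 100-tree random forest over four categories — CART, PLATELET,
RBC, OTHER — trained on 150 labeled crops per category in a 100/50
train/test split. Performance is reported as one-vs-rest sensitivity
TP/(TP+FN) and specificity TN/(TN+FP) for the CART class.

**Quantification.** CART counts summed over a scan are mapped to
concentration through a calibration curve: a power law `y = a·x^b`
(log-log least squares) for buffer samples, or `y = a·ln(x) + b` for
whole blood, whose nonspecific background gives a high blank. Limits of
detection and quantification at 95% certainty come from blank statistics
pushed through the curve: `y_D = blank_mean + 2·1.645·blank_sd`,
`y_Q = blank_mean + 10·blank_sd`, inverted in closed form.

**Fluorescence validation.** Brightfield detections are paired with
fluorescence images via shared coordinates; each cell gets the
dimensionless statistic SD/median of its ROI pixels (gain-invariant;
clustered receptor signal raises it). A two-Gaussian EM mixture fit
separates expressing from non-expressing cells, gated at the intersection
of the weighted component densities.

**Synthetic ground truth.** A generator renders brightfield/fluorescence
tile pairs with the instrument geometry and the four object classes at
controllable density, contrast and noise, plus Poisson-sampled
calibration count tables — every claim above is tested against it.

## Worked example

```r
library(carfind)

# 1. Train the classifier on a labeled synthetic crop library
lib   <- make_object_library(n_per_class = 150, split = c(100, 50), seed = 1)
model <- train_classifier(lib$train$features, lib$train$labels, seed = 1)
evaluate_classifier(model, lib$test$features, lib$test$labels)
#> <carfind_eval> n = 200, accuracy 0.995
#>   CART: sensitivity 1.000, specificity 1.000

# 2. Count CAR T-cells across a simulated 30-tile channel scan
scene <- scene_config(densities = c(CART = 4, PLATELET = 15, RBC = 5, OTHER = 5))
tiles <- lapply(1:30, function(i) render_tile(scene, seed = 5000 + i)$image)
count_sample(tiles, model, sample_id = "spiked_sample")
#> <carfind_counts> spiked_sample: 30 tiles, CART count 126
#>     CART PLATELET      RBC    OTHER
#>      126        0       74       37

# 3. Calibrate on simulated buffer spiking, then report
cal    <- simulate_calibration(cal_sim_config(seed = 2))
spiked <- cal[cal$concentration > 0, ]
fit    <- fit_power(spiked$concentration, spiked$observed)
fit    <- lod_loq(fit, mean(cal$observed[cal$concentration == 0]),
                  sd(cal$observed[cal$concentration == 0]))
fit
#> <calibration_fit> power fit: count = 5.907 * conc^1.01
#>   R^2 = 0.9964 (log-log scale), residual SD 0.164, n = 12
#>   LOD 0.0936, LOQ 0.281 cells/uL (95% certainty; blank 0 +/- 0)

run_pipeline(tiles, model, fit, sample_id = "spiked_sample")
#> <carfind_report> spiked_sample: CART count 126 over 30 tiles
#>   estimated concentration 20.67 cells/uL [quantified]
#>   LOD 0.0936, LOQ 0.281 cells/uL (power fit)
```

The detection step found the spiked cells (126 counted vs. 120 expected
from 4 cells/tile × 30 tiles), the forest kept platelets and debris out
of the CART tally, and the calibration fit inverted the count into a
concentration well above the fitted detection limit.

A command-line wrapper over the same functions lives at
`inst/cli/carfind.R` (subcommands `detect`, `train`, `classify`, `count`,
`calibrate`, `fluor`, `gate`, `simulate`, `run`).

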