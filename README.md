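# grainmetry

Image-based wheat grain morphometry and mean-grain-weight (MGW)
prediction in R.

Wheat MGW — the sample weight divided by the grain count, in mg — is one
of the most frequently measured traits in breeding and physiology.
grainmetry estimates it from ordinary top-view images of non-touching
grains on a bright panel. The pipeline:

* **bicubic resolution enhancement** (factor 10 by default) before
  segmentation, to recover sub-pixel edge positions;
* **HSB brightness thresholding** (iterative intermeans "IsoData" by
  default) and connected-component extraction with traced boundaries;
* **per-grain shape descriptors** in the particle-analysis convention:
  pixel-count area, corner-corrected traced perimeter, area-preserving
  moment-based ellipse fit (`Major`, `Minor`, `Angle`), rotating-calipers
  Feret diameters, circularity, solidity, roundness, aspect ratio,
  intensity skewness/kurtosis;
* a catalogue of **empirical weight-predictive indices** built from those
  descriptors (`Area/Perim.`, `Area*Circ.`, `Perim.*Circ.`, the
  five-factor products `A1`/`A2`, the `Area^1.32` "Kim index" control,
  and more), with ranking against the area-based controls;
* **linear MGW models**: OLS fits with R²/RMSE, k-fold cross-validation,
  and a shipped table of published reference coefficients for the twelve
  retained indices at three measurement scales (original pixels,
  10x-enhanced pixels, SI units);
* a **synthetic scene generator** that renders ground-truthed grain
  images with the size/shape statistics of a real two-year field study,
  so the whole pipeline is testable without an imaging rig.

The scientific core is the linear weight law on grain *width*: with the
fitted-ellipse minor axis in mm,

    MGW = 26.22 * Minor - 37.43        (mg; SI basis)

which predicts MGW more precisely than the classical area-based models
(`MGW = 3.45 * Area - 10.51`, or `Area^1.32`). Width-bearing indices and
the `Area/Perim.` family (note `Area*Circ. = 4π (Area/Perim.)²` and
`Perim.*Circ. = 4π (Area/Perim.)`) consistently outrank plain area.

## Worked example

```r
library(grainmetry)

# a ground-truthed synthetic scene: 450 grains on a 960 x 720 px canvas
sc <- generate_scene(scene_spec(), seed = 1)

# enhance 10x, segment, measure every grain (scale travels with the image)
grains <- measure_image(sc$image, enhance = 10)

# aggregate to the sample and predict MGW from published coefficients
smp <- aggregate_sample(grains, sample_weight = sc$truth$total_weight,
                        sample_id = "demo")
smp$grain_count                                        # 450
smp$mgw                                                # 38.362  (weight/count, mg)
sc$truth$mgw                                           # 38.362  (ground truth)
smp$means$MinFeret_mm                                  # 2.9074  (mean caliper width, mm)
predict_published(smp$means$MinFeret_mm, "MinFeret", "SI")  # 36.652 mg
```

The published-coefficient prediction (36.65 mg) differs from this scene's
true MGW because the generator's weight law is not the field calibration;
fitting the model on simulated samples recovers the generating law:

```r
tab <- simulate_sample_table(180, seed = 1)   # 2x2 design, width-driven law
fit_linear(tab, "Minor", unit_system = "SI")
#> <grain_weight_model> MGW = 26.0268 * [Minor] -36.8501  (SI units)
#>   n = 180, R^2 = 0.7718, RMSE = 1.1019 mg

kfold_cv(tab, "Minor", k = 10, seed = 1)[c("rmse_mean", "rmse_sd")]
#> 10-fold CV RMSE: 1.100 +/- 0.209 mg
```

The recovered slope/intercept sit within one standard error of the
generating values (26.22, −37.43), and the cross-validated RMSE matches
the 1.1 mg residual noise.

Index ranking on a rendered dataset (12 samples, enhancement factor 10)
reproduces the width finding: `Minor` correlates with MGW at R ≈ 0.9997
versus R ≈ 0.95 for `Area`, with `Area*Circ.`, `Perim.*Circ.` and
`Area/Perim.` all above `Area`:

```r
scenes  <- generate_dataset(12, seed = 7)
samples <- process_dataset(scenes, enhance = 10, unit_system = "mm")
rank_indices(samples)
```

## Command line

A thin CLI wraps the same functions (see `exec/grainmetry`):

```sh
grainmetry enhance --factor 10 IN.png OUT.png
grainmetry segment --method default-isodata IN.png MASK.png
grainmetry measure --scale-mm-per-px 0.15 --enhance 10 IN.png OUT.csv
grainmetry indices --unit-system mm OUT.csv IDX.csv
grainmetry rank --mgw-col MGW SAMPLES.csv REPORT.csv
grainmetry fit --index Minor --cv 10 SAMPLES.csv MODEL.json
grainmetry predict --published SI --index Minor VALUES.csv PRED.csv
grainmetry simulate --n-samples 12 --seed 42 OUTDIR
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/raster_io.R` | image/table I/O, bicubic enhancement |
| `R/segmentation.R` | thresholding, hole filling, labelling, boundary tracing |
| `R/descriptors.R` | per-grain shape and intensity descriptors |
| `R/indices.R` | predictive index catalogue and ranking |
| `R/models.R` | aggregation, OLS fits, cross-validation, published coefficients |
| `R/synthetic.R` | ground-truthed scene and dataset generators |
| `src/kernels.cpp` | bicubic, flood-fill labelling, Moore tracing (Rcpp) |
| `vignettes/grain-morphometry.Rmd` | methods: models, conventions, design choices |

See the methods vignette for the measurement conventions, the generator's
statistical design, and the reasoning behind the package's numerical
choices.
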