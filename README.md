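# opcrkin

Dental topographic analysis asks how complex a tooth row's occlusal surface
is and what shapes that complexity. **opcrkin** implements the full pipeline
for carnivorous mammals: it computes **orientation patch count (OPC)** and
its rotation-averaged form **OPCR** from gridded 3-D tooth-row surfaces,
derives relative measures of mandibular motion from specimen measurements,
and compares candidate regression hypotheses of tooth-row complexity by
maximum-likelihood GLS and small-sample AIC (AICc) multimodel inference.

It is written for functional morphologists working with laser-scanned tooth
rows (point clouds, PLY meshes, Surfer grids) and for anyone who wants a
reproducible, scriptable version of the classic OPCR + model-selection
workflow.

## The measures and the models

**OPC** treats the occlusal surface as a digital elevation model: each grid
cell gets the azimuth of steepest descent (its *aspect*), aspects are binned
into 8 compass classes, and OPC is the number of connected same-class
patches (components under edge adjacency, at least 3 cells by default). Low
OPC ~ slicing teeth (faunivory), high OPC ~ grinding teeth (herbivory).
**OPCR** averages OPC over 8 rotations of the binning at multiples of
5.625°, removing sensitivity to specimen alignment. Tooth rows are
standardized to 50 data rows per tooth so rows of different length are
comparable.

Specimen-level predictors are the opposing row's log OPCR and three
kinematic measures: relative lateral translation *rt* = ln(*t*/*w*),
relative ventral rotational distance *rd* = ln(*d*/*w*), and log sagittal
occlusal angle ln *a* (with *w* the glenoid fossae width, a body-size
proxy). Five candidate models per response (upper or lower ln OPCR),

> m1: ~ opposing; m2: + *rt*; m3: + *rd*; m4: + *rt* + *rd*; m5: + ln *a*

are fitted by ML — OLS for m1, GLS with a Gaussian residual correlation
`exp(-(s/ρ)²)` for the multi-predictor models — and ranked by

> AICc = −2 logLik + 2K + 2K(K+1)/(n−K−1),

with Akaike weights, 95% confidence sets, and weighted model averaging.

## Worked example

A four-faced pyramid has four uniform-aspect faces centred on four
orientation bins, so every rotation sees exactly 4 patches:

```r
library(opcrkin)
pyr <- make_surface(surface_spec("pyramid", n_faces = 4))
compute_opcr(pyr)
#> <opcr_result> OPCR = 4 over 8 rotations (step 5.625 deg)
#>   per-rotation OPC: 4 4 4 4 4 4 4 4
```

The packaged table (`inst/extdata/table1_specimens.csv`) holds 34 specimens
— 20 Carnivora, 14 Dasyuromorphia — with tooth counts, OPCR values and the
four occlusion measures. The one-call analysis:

```r
rep <- analyze_specimens("table1")
rep$selection_upper
#> Model selection for upper tooth-row ln OPCR (correlation: maximum over candidate_covariates)
#>  model intercept opp_opcr     rt     rd  ln_a df logLik    AICc   rho delta_AICc weight in_conf_set
#>      3     0.896    0.782     NA -0.225    NA  5 26.945 -41.746 0.065      0.000  0.784        TRUE
#>      4     0.831    0.790 -0.022 -0.210    NA  6 26.987 -38.863 0.065      2.883  0.185        TRUE
#>      2     0.657    0.837 -0.169     NA    NA  5 23.427 -34.712 0.078      7.034  0.023       FALSE
#>      1     1.368    0.789     NA     NA    NA  3 19.428 -32.055    NA      9.691  0.006       FALSE
#>      5     1.249    0.751     NA     NA 0.088  5 20.641 -29.140 0.107     12.607  0.001       FALSE
```

Reading the table: the best-supported hypothesis of upper tooth-row
complexity (model 3, Akaike weight 0.78) pairs the opposing row's
complexity (slope 0.78) with relative ventral rotational distance (negative
slope: more relative ventral motion, simpler upper row, holding the lower
row fixed). The complexity-only model 1 carries essentially no weight —
mandibular motion earns its place in the model. The same ranking logic for
the lower response puts model 3 first with models 2 and 4 inside the
confidence set. `rep$tests` holds the Mann-Whitney comparisons of the two
orders (Carnivora first), `rep$correlations` the size correlations, and
`model_average(rep$selection_upper)` the weight-averaged coefficients.

Surfaces come in through `read_ply()`, `read_xyz()` or
`read_surfer_grid()`; `run_opcr("row.ply", n_teeth = 4)` goes from file to
OPCR in one call. `simulate_specimens()` generates tables with known
coefficients for calibration studies.

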