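# angiomorph

Fully automatic morphometry of vessel inclination in fundus angiograms, for
ophthalmic image-analysis researchers studying retinal markers of systemic
disease (here: arterial hypertension).

In a fluorescein angiogram, vessels appear as bright Gaussian ridges
radiating from the optic disc. angiomorph assigns every vessel pixel a
tangent orientation with an oriented matched-filter bank — the mask at
orientation θ weights offset (m, n) by

    g(d) = ε_mi + (ε_ma − ε_mi) · exp(−d² / 2σ²),   d = m·cosθ + n·sinθ,

sweeping θ = 0°…179° in 1° steps and keeping per pixel the maximal response
L_ma and its orientation L_θ. Otsu's threshold on L_ma gates the orientation
field into the tangent map L_w; each retained angle is then folded against
the ray from the optic-disc centre into the radial-relative map L_k ∈
[0°, 90°] (0° = vessel radiates from the disc, 90° = concentric). Inside the
standard 2r–3r annulus about the disc, per-image features are computed:

* `z` — number of vessel objects (8-connected components),
* `phi_sr`, `phi_std` — mean and SD of per-object mean angles,
* `phi_max` — mode of the 1°-bin angle histogram,
* `p_s` — percentage of annulus area covered by vessels.

A CART decision tree (Gini impurity, cost-complexity pruning at the
one-standard-error level, stratified cross-validation) classifies subjects
healthy vs hypertensive from these features, with the usual confusion panel
(TPR, FPR, ACC, SPC, PPV, NPV, FDR) and Student-t confidence-band separation
of the groups.

A synthetic-phantom generator (`generate_phantom()`) renders vessels of known
per-pixel tangent angle, width and count, so every stage is validated against
analytic ground truth without clinical data.

## Worked example

```r
library(angiomorph)

# a 512x512 phantom under acquisition-like conditions: 12 radial vessels,
# disc radius 60 px, noisy unevenly lit background
truth <- generate_phantom(phantom_spec(seed = 7))
res <- analyze_vessels(truth$image, phantom_disc(truth), run_config(sigma = 2))
tidy(res$metrics)
#> # A tibble: 1 × 6
#>       z phi_sr phi_std phi_max   p_s annulus_pixel_count
#>   <int>  <dbl>   <dbl>   <int> <dbl>               <int>
#> 1    12  0.637   0.135       0  5.26               56536
```

All 12 phantom vessels are found (`z = 12`); because they radiate from the
disc, their radial-relative angles sit near 0° (`phi_sr` ≈ 0.6°, histogram
mode 0°), and they cover 5.3% of the measurement annulus.
`autoplot(res$metrics)` draws the angle histogram, `autoplot(res$lk)` the
radial angle map.

```r
# a 52-subject cohort drawn with the hypertension-study group statistics
# (phi_max: healthy 6.8 ± 5.1°, hypertensive 24.3 ± 3.0°; n = 40/12)
cohort <- simulate_cohort(seed = 1)
evaluate_attribute_trees(cohort, seed = 1)
#> # A tibble: 6 × 10
#>   tree       tp    tn    fp    fn   acc n_leaves root_attribute root_threshold
#> 1 z           0    40     0    12 0.769        1 <NA>                     NA
#> 2 phi_sr      0    40     0    12 0.769        1 <NA>                     NA
#> 3 phi_std     0    40     0    12 0.769        1 <NA>                     NA
#> 4 phi_max    12    40     0     0 1            2 phi_max                  18.5
#> 5 p_s         0    40     0    12 0.769        1 <NA>                     NA
#> 6 all        12    40     0     0 1            2 phi_max                  18.5
```

Only the informative attribute survives pruning: the `phi_max` tree keeps a
single split (threshold 18.5° here), while the noise attributes collapse to
single-leaf trees predicting the majority class (accuracy 40/52 ≈ 0.77).

```r
separation_bands(c(6.8, 5.1, 40), c(21.6, 7.6, 12), alpha = 0.001,
                 groups = c("healthy", "hypertensive"))
#>   group         mean    sd     n    df t_crit lower upper
#> 1 healthy        6.8   5.1    40    39   3.56  3.93  9.67
#> 2 hypertensive  21.6   7.6    12    11   4.44 11.9  31.3
#> bands disjoint: TRUE
```

The two groups' 99.9% confidence bands do not overlap.

## Command line

A thin CLI over the same functions supports batch work:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "angiomorph.R", package = "angiomorph"))')
Rscript $CLI phantom  --out data --vessels 12 --size 512 --seed 1
Rscript $CLI analyze  --image data/phantom_image.tif --disc-center 256.5,256.5 --disc-radius 60 --out results
Rscript $CLI batch    --images data --geometry data/phantom_geometry.csv --out results
Rscript $CLI classify --metrics cohort.csv --out results --seed 1
```

Inputs are PNG/TIFF; angle maps are saved as 16-bit TIFF (sentinel 65535 =
background), metrics and histograms as CSV, classification reports as JSON.

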