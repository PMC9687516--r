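# eotrhtex

Texture analysis of equine incisor radiographs for grading **Equine
Odontoclastic Tooth Resorption and Hypercementosis (EOTRH)**, a degenerative
dental syndrome of older horses scored radiographically from grade 0
(normal) to grade 3 (severe). Resorption shows as low-radiopacity defects
and hypercementosis as bright bulbous deposits; their alternating mosaic
makes the radiographic texture of a diseased tooth progressively more
irregular. This package quantifies that irregularity and is aimed at
veterinary imaging researchers building quantitative or automated EOTRH
scoring.

## What it computes

For each rectangular tooth region of interest (ROI), after one of three
preprocessing filters (Normalize to zero mean/unit variance; 3×3 median;
Laplacian sharpening `img − w·∇²img`):

* **Five two-dimensional entropies** — sample entropy
  `SampEn2D = −ln(B/A)` (crisp Chebyshev matches of m×m vs (m+1)×(m+1)
  windows at tolerance `r = 0.2·SD`), fuzzy entropy
  `FuzzEn2D = −ln(φ_{m+1}/φ_m)` with graded similarity `exp(−d^n/r)`,
  permutation entropy (Shannon entropy of ordinal window patterns),
  dispersion entropy (entropy of normal-CDF class patterns), and
  distribution entropy `DistEn2D = −Σ p_t log₂ p_t / log₂ M`, the
  normalized entropy of the histogram of all pairwise inter-window
  distances.
* **Six GLCM texture features** as the comparison baseline: Cluster
  Prominence, Contrast, Difference Average, Difference Entropy, Difference
  Variance, Inverse Variance.
* **Grade-wise statistics**: Shapiro–Wilk-gated ANOVA/Tukey or
  Kruskal–Wallis/Dunn comparisons with compact letter displays, a
  monotone-increase flag, and sequential slope/intercept similarity tests
  between the entropy and GLCM grade trends.
* **Threshold detection** of grade 3 vs grade 0 at mean, mean + SD and
  mean + 2 SD thresholds, reporting Se, Sp, PPV and NPV.

A **synthetic phantom generator** produces graded tooth ROIs (dark
resorption-like lesions, bright apical hypercementosis-like blobs,
grade-scaled counts and noise) so the full pipeline is testable without
clinical radiographs. See the vignette `vignettes/texture-grading.Rmd` for
the model details and design choices.

## Worked example

```r
library(eotrhtex)
library(dplyr)

dir <- file.path(tempdir(), "demo")
manifest <- generate_cohort(dir, c("0" = 8, "1" = 8, "2" = 8, "3" = 8),
                            base_seed = 7)
features <- extract_features(file.path(dir, "manifest.csv"))
head(features, 5)
#> # A tibble: 5 × 7
#>   horse_id tooth grade filter    measure  value note
#>   <chr>    <int> <int> <chr>     <chr>    <dbl> <chr>
#> 1 H001       101     0 normalize SampEn2D 0.120 <NA>
#> 2 H001       101     0 normalize FuzzEn2D 0.161 <NA>
#> 3 H001       101     0 normalize PermEn2D 3.17  <NA>
#> 4 H001       101     0 normalize DispEn2D 1.19  <NA>
#> 5 H001       101     0 normalize DistEn2D 0.684 <NA>
```

Each ROI yields 15 entropy rows (5 measures × 3 filters) and 18 GLCM rows
(6 features × 3 filters). Comparing normalized-filter DistEn2D between
grades:

```r
disten <- filter(features, measure == "DistEn2D", filter == "normalize")
compare_groups(disten, value, grade)
#> Grade comparison (kw_dunn), omnibus p = 2.14e-06
#> # A tibble: 4 × 5
#>   group     n  mean      sd letters
#>   <int> <int> <dbl>   <dbl> <chr>
#> 1     0     8 0.685 0.00266 a
#> 2     1     8 0.726 0.00898 ab
#> 3     2     8 0.807 0.0176  bc
#> 4     3     8 0.865 0.0115  c
#> Monotone increase across groups: yes
```

DistEn2D rises strictly with phantom grade; groups that share a letter are
not significantly different at α = 0.05, and the monotone flag marks a
significant grade-related increase. Thresholding the same measure for
grade 0 vs grade 3 detection:

```r
format_detection_table(detect_grades(features, "DistEn2D", "normalize"))
#> # A tibble: 12 × 3
#>    rule          metric shown
#>  1 mean          Se     1.00
#>  2 mean          Sp     1.00
#>  3 mean          PPV    1.00
#>  4 mean          NPV    1.00
#>  5 mean_plus_sd  Se     0.25
#>  6 mean_plus_sd  Sp     1.00
#>  7 mean_plus_sd  PPV    1.00
#>  8 mean_plus_sd  NPV    0.57
#>  9 mean_plus_2sd Se     0.00
#> 10 mean_plus_2sd Sp     1.00
#> 11 mean_plus_2sd PPV    -
#> 12 mean_plus_2sd NPV    0.50
```

Sensitivity falls and specificity rises as the threshold increases; ratios
with a zero denominator are printed as `-`. (Phantoms separate far more
cleanly than clinical radiographs — these values characterize the synthetic
cohort, not clinical performance.)

A thin command-line wrapper with subcommands `phantom`, `extract`, `stats`,
`detect` and `all` is installed at `inst/cli/eotrhtex`.

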