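# profilecad

Quantification of membrane-protein expression and spatial distribution
from two-channel *in situ* immunofluorescence images.

## The problem

Missense variants of membrane proteins — the motivating case is
E-cadherin (*CDH1*), whose germline variants underlie hereditary diffuse
gastric cancer — often change the protein's *localization* rather than
abolishing its expression: pathogenic variants show reduced fluorescence
at the plasma membrane and sometimes an aberrant perinuclear
accumulation (endoplasmic-reticulum retention). Scoring such phenotypes
by eye is subjective. `profilecad` implements a bioimaging pipeline that
turns an IF image pair (nuclear counterstain + protein channel) and a
set of operator-selected cells into quantitative, population-level
descriptors, without ever attempting the unreliable step of segmenting
mutant cell boundaries.

## The method

For selected pairs of neighboring cells, the **internuclear (IN)
profile** samples the protein channel along the segment joining the two
nucleus centroids (segmented by Otsu thresholding + watershed), crossing
both cytoplasms and the shared membrane. For single cells, **radial
(RD) profiles** sample rays from the nucleus centroid at equally spaced
angles. Each profile is resampled to a constant length of L = 100
positions; on the IN axis the membrane sits near x = 0.5.

Profiles are stacked as columns of a map **M** (100 x N) and processed
as:

1. *Denoising* under the Poisson noise model: Anscombe transform
   z = 2·sqrt(v + 3/8), exact 1D total-variation smoothing per column,
   unbiased closed-form inverse.
2. *Geometric compensation*: each column j gets a monotone
   piecewise-linear warp w_j (fixed endpoints, 5 interior knots,
   per-knot displacement ≤ 0.15) chosen to minimize

       sum_x [ M(w_j(x), j) − mean_profile(x) ]²  +  λ ||d_j||²

   iterated against the evolving mean until the row-wise variability of
   the map stops decreasing. This aligns the membrane peak across a
   heterogeneous cell population.
3. *Descriptors* per profile: membrane mean fluorescence (mean over
   |x − 0.5| ≤ 0.05) and the **MMR** (maximum-mean ratio),

       MMR = max(profile) / mean(profile)  ≥ 1,

   the sharpness of the membrane peak (scale-invariant; 1 for a
   flat profile). Populations are compared feature-wise against a
   reference with two-sided Mann–Whitney tests (exact by enumeration for
   small samples) under Bonferroni correction.
4. *Virtual cell*: per-angle average compensated RD profiles are
   inverse-polar-mapped onto a disk (radius 100 px), yielding a
   qualitative portrait of the typical cell's protein distribution, plus
   a percentile-stretched contrast-enhanced version.

A synthetic-data module (`make_scene()`, `render_channels()`,
`write_fixture()`) simulates confluent monolayers with known ground
truth — WT-like membrane-concentrated and mutant-like
perinuclear-accumulation phenotypes, Poisson photon noise — so the whole
pipeline is testable end to end.

## Worked example

```r
library(profilecad)

dir_wt <- tempfile(); dir_mut <- tempfile()
write_fixture(make_scene(9, c(256, 256), 0.2, seed = 1),
              wt_phenotype(noise_model = "poisson"), dir_wt)
write_fixture(make_scene(9, c(256, 256), 0.2, seed = 2),
              mutant_phenotype(noise_model = "poisson"), dir_mut)

paths <- function(d) list(nuclear = file.path(d, "nuclear.tif"),
                          protein = file.path(d, "protein.tif"),
                          selections = file.path(d, "selections.csv"))
cfg <- run_config(populations = list(WT = paths(dir_wt),
                                     mutant = paths(dir_mut)),
                  reference = "WT", ray_length = 45, n_angles = 16,
                  seed = 1)
manifest <- run_pipeline(cfg)
manifest$summary
tidy(manifest$comparisons)
```

```
#> # A tibble: 2 x 6
#>   population n_profiles membrane_mean_mean membrane_mean_se mmr_mean mmr_se
#>   <chr>           <int>              <dbl>            <dbl>    <dbl>  <dbl>
#> 1 WT                 16              1236.             3.52     3.61 0.0201
#> 2 mutant             16               987.            12.6      3.04 0.0226
#> # A tibble: 2 x 7
#>   population feature statistic   p_raw n_comparisons alpha_corrected significant
#>   <chr>      <chr>       <dbl>   <dbl>         <int>           <dbl> <lgl>
#> 1 mutant     membra~         0 1.54e-6             2           0.025 TRUE
#> 2 mutant     mmr             0 1.54e-6             2           0.025 TRUE
```

The summary mirrors a quantification table: per population, the number
of IN profiles, membrane mean fluorescence ± SE (here in stored TIFF
counts, 16 per generator intensity unit) and MMR ± SE. The WT-like
population shows the higher membrane mean and the higher MMR — the
sharp, regular membrane peak of a properly trafficked adhesion protein —
and both feature differences are significant at the Bonferroni-corrected
level (`alpha / 2` for this two-test batch). `autoplot()` methods
display profile maps, average profiles with SD bands, and virtual
cells; per-population intermediates (maps, warps, features, report) are
persisted under `cfg$out_dir`.

A command-line interface wrapping these functions is provided at
`inst/cli/profilecad.R` with subcommands `simulate`, `segment`,
`profiles`, `compensate`, `virtualcell` and `run`.

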