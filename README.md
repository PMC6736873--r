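# neomyelin

Quantitative analysis of **myelin-like signals (MLS)** on T2-weighted
neonatal brain MRI. In preterm neonates (roughly 29–44 weeks gestational
age, GA), myelinating tissue in the deep brain — the ventrolateral nuclei
(VLN), subthalamic nuclei (STN) and posterior limbs of the internal capsule
(PLIC) — and in the brainstem appears hypointense on T2-weighted images.
Segmenting it, tracking its volume, and modelling where and when it appears
gives quantitative markers of brain maturation.

The package is aimed at researchers in neonatal neuroimaging who have
already-extracted, bias-corrected, spatially aligned volumes (NIfTI) and
want the downstream modelling; it also ships a fully synthetic phantom
module so the entire pipeline runs and is tested without any clinical data.

## The model

Segmentation is a three-class Gaussian mixture over MLS, an explicit
partial-volume class (PV) and background (BKG), fitted by
expectation-maximization with two structural constraints,

  μ_PV = (μ_MLS + μ_BKG)/2,  σ²_MLS = σ²_PV = σ²_BKG,

and a second-order Markov-random-field spatial prior. Neighbor posteriors
are aggregated over the 26-neighborhood with inverse-distance weights,
v_k = Σ_j p_jk / d_ij, and the energy of class k is the quadratic form
vᵀ T_k v of a 3×3×3 **connectivity tensor** T_k(k1,k2) that penalizes
implausible class triplets (penalties t1 = 0.05, t2 = 0.03, t3 = 0.01 by
default) — PV is encouraged exactly where MLS and BKG meet and discouraged
elsewhere. Posterior maps are converted to a final mask by maximum vote
plus linear unmixing of PV voxels: a PV voxel with MLS fraction
f = (μ_BKG − y)/(μ_BKG − μ_MLS) strictly above 0.5 joins the MLS mask.

On top of the segmentations the package builds a voxelwise logistic
**growth atlas** P(MLS at t) = c/(1 + exp(−k(t − t0))), extracts
myelination milestones (with left-censoring), predicts gestational age by
sum-of-squared-differences matching against the atlas, and fits
exponential volume trends y = a·e^(bx) with R².

## Worked example

```r
library(neomyelin)

# a seeded T2-like phantom: 40 x 40 x 20 voxels at 0.86 x 0.86 x 1 mm,
# deep-brain-like structures, noise at 5% of the MLS/BKG contrast
ph  <- generate_phantom(phantom_spec(seed = 1))
fit <- run_em(ph$image, ph$roi)
tidy(fit)
#> # A tibble: 3 × 3
#>   class  mean sigma2
#>   <chr> <dbl>  <dbl>
#> 1 MLS    102.   33.6
#> 2 PV     151.   33.6
#> 3 BKG    200.   33.6

seg <- finalize_mls(fit)
dice(seg$mask, truth_mask(ph))
#> [1] 0.9773178
```

The fitted means recover the generating values (100, 150, 200) to within
2%, and the final mask overlaps the geometric ground truth at Dice ≈ 0.98.
A longitudinal experiment is just as short:

```r
ref    <- phantom_spec(grid_shape = c(24, 24, 12), seed = 1)
onsets <- tibble::tibble(label = c("VLN", "STN", "PLIC"),
                         t0 = c(26, 28, 40), k = 3, c = 1)
coh    <- generate_cohort(cohort_spec(60, c(29, 44), onsets, seed = 2), ref)
atlas  <- build_atlas(coh)
milestone(atlas, attr(coh, "structure_masks")$PLIC)
#> # A tibble: 1 × 3
#>   status  ga_weeks label
#>   <chr>      <dbl> <chr>
#> 1 reached     40.4 40.4 weeks
```

`autoplot()` methods cover fitted segmentations, SSD curves, leave-one-out
predictions and volume trends; `tidy()`/`glance()` give broom-style
summaries throughout. A thin command-line wrapper lives at
`inst/cli/neomyelin.R` (subcommands `simulate-phantom`, `segment`,
`evaluate`, `atlas-build`, `predict-ga`, `trend`, ...).

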