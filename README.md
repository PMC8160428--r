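# germfilter

Trait-based analysis of **seed germination strategies along experimental
nitrogen-addition gradients**, for community ecologists studying how
fertilization acts as an environmental filter in grasslands and alpine
meadows.

A study of this design produces two tables: laboratory germination trials
(replicate dishes of seeds incubated at 5/10/15/20/25 °C constant and a
5/25 °C alternating regime, with a dry-warm vs dry-warm + wet-cold storage
contrast, checked daily for 60 days) and vegetation quadrats (individual
counts per species in 5 blocks × 4 nitrogen doses, 0–20 g N m⁻² yr⁻¹).
`germfilter` turns them into species- and community-level evidence about
which germination traits nitrogen selects for.

## What it computes

**Species level.** Germination percentage GP = G_fin/n and the
day-weighted germination rate GR = (1/n) Σᵢ Gᵢ/i per condition; the
normalized-difference responses to the alternating regime,
R₅/₂₅ = (GP₅/₂₅ − GP₁₅)/(GP₅/₂₅ + GP₁₅), and to wet-cold storage (R_wc);
the temperature-niche metrics Oⱼ = gⱼ/g_max, Pⱼ = Oⱼ/ΣOⱼ and breadth
BTN = (1/R) ΣOⱼ (R = 5); and the fertilization response
R_f = (RA_N3 − RA_N0)/(RA_N3 + RA_N0) from quadrat abundances.

**Community level.** Abundance-weighted means (CWM) of 23 trait variables
per quadrat, and the functional diversity indices FRic (convex-hull
volume), FEve (minimum-spanning-tree evenness) and FDiv (divergence) in a
shared 7-trait space, with the hull computed by a built-in d-dimensional
beneath-beyond algorithm (RcppArmadillo).

**Inference.** Beta regression of the transformed fertilization response
(y + 1)/2 on each germination index, fitted by maximum likelihood with
analytic gradients (boundary species removed first); Gaussian linear mixed
models with a block random intercept fitted by profiled ML, with
likelihood-ratio χ² tests and Tukey compact-letter comparisons; and
correlation-matrix PCA of the CWM profiles.

**Synthetic studies.** A seeded generator reproduces the full design
(63 species, 5 × 4 plots, 3 × 50 seeds per condition) with configurable
couplings between true germination traits and nitrogen response, so every
inferential stage is validated by parameter recovery.

## Worked example

```r
library(germfilter)
run <- run_study(sim = sim_config(rng_seed = 1))
run
#> germination-trait filtering analysis
#>   63 species, 20 quadrats, 25 species-level fits

subset(run$species_fits, predictor %in% c("gp_5", "gr_10", "r_wc", "btn"),
       c(predictor, slope, z_slope, p_slope, pseudo_r2, n_used))
#>  predictor slope z_slope p_slope pseudo_r2 n_used
#>       gp_5  1.20    1.48 0.13985    0.0734     35
#>      gr_10  3.00    2.11 0.03489    0.1378     35
#>       r_wc -3.09   -1.91 0.05649    0.1361     35
#>        btn  4.73    2.94 0.00333    0.2376     35
```

Each row is one beta regression of the transformed fertilization response
on a germination index over the 35 species with usable data (28 of 63 were
dropped as undefined or boundary ±1 cases).  Under the default generator
coupling, niche breadth (`btn`) is the strongest positive predictor of
surviving fertilization — species germinating across many temperatures gain
relative abundance under high nitrogen — while the wet-cold storage
response trends negative.

```r
subset(run$community_fits, response %in% c("cwm_gp", "cwm_btn", "fric"))
#>  response                      term  chi2 df        p
#>    cwm_gp               temperature 219.5  4 2.43e-46
#>    cwm_gp             fertilization 218.5  3 4.15e-47
#>    cwm_gp temperature:fertilization 160.3 12 4.62e-28
#>   cwm_btn             fertilization  97.4  3 5.49e-21
#>      fric             fertilization  58.3  3 1.37e-12

aggregate(fric ~ n_level, run$fd, mean)
#>   n_level   fric
#> 1      N0 15.268
#> 2      N1 13.105
#> 3      N2  6.430
#> 4      N3  0.443

run$pca
#> correlation-matrix PCA: 23 variables, 20 quadrats
#>   PC1 79.68%, PC2 12.00% (first two: 91.68%)
```

The mixed-model χ² values test each term by comparing nested ML fits with
block as a random intercept; the functional-richness gradient shows the
occupied germination-trait volume collapsing toward the high-nitrogen
plots.

`run_pipeline("out/", seed = 42)` writes the same results as CSVs plus a
`manifest.json`, byte-identically for a fixed seed, and
`report("out/manifest.json")` renders a markdown summary.  A thin CLI
wrapper lives at `inst/scripts/germfilter.R`.

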