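# mammodose

Average glandular dose (AGD) — the mean absorbed dose to the glandular
tissue of the compressed breast — is the reference patient-dose quantity in
digital mammography. It cannot be measured directly; it is computed from the
incident air kerma through Monte-Carlo-derived conversion factors, and the
dominant uncertainty is the *glandularity* (glandular mass fraction) each
dosimetry protocol assumes. `mammodose` is an R package for medical
physicists and dose-registry analysts that computes AGD three ways per
exposure and quantifies how far the methods diverge on a cohort:

1. **Dance formalism, population glandularity**
   `AGD = IAK · g(T, HVL) · c(G, T, HVL) · s(anode/filter)`, with `G` from
   the age-group × thickness table;
2. **Wu/equipment formalism** `AGD = X_ESE · DgN`, read from the equipment
   (pass-through) or recomputed with a pluggable DgN table at the
   densest-region glandularity (`min(2·G, 100)` heuristic);
3. **Personalized** — the Dance formalism with glandularity measured from
   the projection image via the two-tissue inversion
   `h_d = ln(P/P_fat) / (μ_fat − μ_dense)`, integrated to volumetric breast
   density and converted to percent by weight.

The package ships the published conversion-factor grids (exactly reproduced
at every node), a two-tissue phantom generator and density estimator, a
calibrated synthetic cohort generator (no patient data are included or
required), stratified ratio/regression/correlation analyses, CSV and
DICOM-header readers, and a small CLI (`inst/cli/mammodose.R`).

## Worked example

```r
library(mammodose)

ft <- load_factor_tables("paper-default")
g_factor(ft, thickness = 40, hvl = 0.5)      # 0.319
c_factor(ft, 50, 40, 0.5)                    # 1.00  (50% glandularity)
dance_glandularity(ft, age = 55, thickness = 30)  # 72 % by weight

cohort <- generate_cohort(cohort_params(), seed = 1)   # n = 3050
agd <- compute_agd_table(cohort$records, ft)
summarize_ratios(agd, "ratio_dance_volpara")
```

```
                ratio class    n   min   max  mean     sd
1 ratio_dance_volpara 20-40  336 0.793 0.984 0.875 0.0341
2 ratio_dance_volpara 41-60 1504 0.793 1.074 0.932 0.0404
3 ratio_dance_volpara 61-80 1090 0.872 1.125 0.973 0.0388
4 ratio_dance_volpara   >80  120 0.937 1.106 0.990 0.0280
```

For thin breasts the population model assigns much higher glandularities
than the image-based measurement, so its `c` factor — and hence its AGD —
is lower: the Dance/personalized ratio averages 0.88 at 20–40 mm and
approaches 1 for the largest breasts. The regression refit on the same
cohort,

```r
fit_glandularity_regression(cohort$records)
#> glandularity = 59.775 -0.3267 * age -0.4404 * thickness   (n = 3050)
#>   SE: 1.017 / 0.0133 / 0.0119   R^2 = 0.404, ANOVA p = 0
```

recovers the generator's observable-scale coefficients
(59.6, −0.332 %/year, −0.431 %/mm). Image-based density estimation:

```r
ph <- synth_phantom(phantom_spec(thickness_mm = 50,
        dense_regions = list(list(x0 = 10, x1 = 30, y0 = 10, y1 = 30,
                                  hd = 25))), seed = 1)
estimate_density(ph$image, ph$atten)
#> <density_result> VBD 5.71 % by volume, GPW 7.91 % by weight
#>   dense 10000 mm^3 of 175232 mm^3; clamped 0 low / 0 high
```

See `vignettes/mammography-dose-comparison.Rmd` for the models, the
interpolation scheme, generator calibration and known limitations.

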