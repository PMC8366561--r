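# texhist

Filtration-histogram texture analysis of paired CT and PET tumor slices,
with a prognostic survival screen — an open, tested R implementation of the
radiomics workflow used to study tumor heterogeneity as a survival biomarker
(e.g. in metastatic neuroendocrine tumors imaged by somatostatin-receptor
PET-CT before radionuclide therapy).

## Who this is for

Imaging scientists and biostatisticians who want a transparent, scriptable
version of the "filtration-histogram" technique popularized by commercial
texture-analysis software: single-slice 2-D lesion ROIs, a
Laplacian-of-Gaussian (LoG) band-pass at several spatial scales, first-order
histogram statistics, and a median-split Kaplan-Meier screen with
false-discovery-rate control and stepwise Cox selection. Because clinical
imaging cohorts are rarely shareable, the package also ships a synthetic
phantom/cohort generator with a known latent-heterogeneity ground truth, so
the entire pipeline is testable end to end.

## The method

**Filtration.** Each CT slice is convolved with a scale-normalized,
DC-free LoG kernel

&nbsp;&nbsp;&nbsp;&nbsp;K_σ = −σ² ∇²G_σ,&nbsp;&nbsp;σ = SSF/2,

at spatial scale filter (SSF) values 2 mm (fine), 3–5 mm (medium) and 6 mm
(coarse), plus the unfiltered slice as a control. The band-pass enhances
image objects of size comparable to the SSF: a Gaussian object of diameter
2σ responds maximally at the matching scale. PET slices are analyzed
unfiltered (their intrinsic resolution is too coarse for sub-centimeter
band-pass scales).

**Quantification.** Within the lesion ROI (CT pixels below −50 HU — air and
gas — are excluded, decided on the unfiltered slice and reused at every
scale), each map is summarized by six statistics: mean, SD (population),
entropy (−Σ pᵢ log₂ pᵢ over 64 equal-width bins), mean of positive pixels
(MPP), skewness and excess kurtosis. That gives 6 × 6 = 36 CT features and
6 PET features per lesion, plus SUVmax, SUVmean and the PET uptake area in
pixels.

**Survival analysis.** Lesion features are averaged per patient (up to the
five most PET-avid lesions). Each marker is dichotomized at its cohort
median; groups are compared by Kaplan-Meier curves and the log-rank test;
p-values are Benjamini-Hochberg adjusted within each endpoint family at
FDR q = 0.30; and the BH-significant markers enter stepwise forward-Wald
Cox regression (entry p < 0.05, Breslow ties) to find independent
predictors, reported as HR with 95% CI.

## Worked example

Simulate a 44-patient cohort in which the latent heterogeneity z drives the
overall-survival hazard (HR 2.5 per SD of z), extract features, and run the
screen:

```r
library(texhist)
run <- run_pipeline(config = run_config(seed = 7),
                    sim_cohort_spec = cohort_spec(n = 44, beta_os = log(2.5)))
print(run$screens$os)
```

```
<texhist_screen> endpoint OS, 45 markers tested, 1 skipped, FDR q = 0.3
            marker   cutoff median below (n) median above (n)        p    p_adj
  ct_ssf0_kurtosis    >4.49     79.8788 (22)     17.9113 (22) 1.33e-05 0.000441
   ct_ssf0_entropy   <=4.62     16.5519 (22)       60.64 (22) 1.96e-05 0.000441
       ct_ssf0_mpp    >40.4     79.8788 (22)     17.9935 (22) 6.48e-05 0.000972
 pet_ssf0_kurtosis   >-1.16     57.9334 (22)     17.9113 (22) 4.64e-04 0.005220
        ct_ssf0_sd    >12.2       60.64 (22)     17.9113 (22) 1.55e-03 0.013900
  ct_ssf2_kurtosis    >8.23      54.705 (22)     17.9113 (22) 3.82e-03 0.028600
   ...
```

Each row is one marker: the median cut-off (the `>`/`<=` sign marks the
poor-prognosis side), per-group median survival in months with group sizes,
the raw log-rank p and its BH-adjusted value. Here high unfiltered-CT
kurtosis flags the poor-prognosis group (median survival 17.9 vs 79.9
months), exactly the heterogeneity-to-hazard link the generator built in.
The forward-Wald Cox step then picks the independent predictor:

```r
print(run$cox$os)
```

```
<texhist_cox_selection> entered: ct_ssf0_kurtosis
<texhist_cox> 1 covariate(s), ties = breslow
         covariate coef    se                hr        p
1 ct_ssf0_kurtosis 1.68 0.422 5.38 (2.35-12.32) 6.76e-05
```

i.e. patients above the kurtosis median have a 5.4-fold instantaneous risk
of death (95% CI 2.35–12.32).

Single-lesion use is just as direct:

```r
les <- make_lesion_phantom(z = 1, seed = 3)   # one heterogeneous lesion
f   <- extract_features(les)
round(f[c("ct_ssf6_kurtosis", "pet_ssf0_entropy", "suv_max",
          "suv_mean", "uptake_area_px")], 3)
#> ct_ssf6_kurtosis pet_ssf0_entropy          suv_max         suv_mean
#>            5.078            4.625            8.076            5.209
#>   uptake_area_px
#>           32.000
```

A command-line front end with `simulate` / `extract` / `survival` /
`run-all` subcommands lives at `inst/cli/texhist.R`.

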