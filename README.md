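# nnufti

Quantitative detection support for liver SPECT read-outs that visual
inspection gets wrong. In somatostatin-receptor scintigraphy
(e.g. ^111^In-octreotide), small or low-contrast neuroendocrine tumour
deposits in the liver hide inside intense, non-uniform, noisy hepatic
uptake; a worrying fraction of "negative" livers later turn out to carry
tumours. `nnufti` implements a segmentation statistic that flags such
livers from the reconstructed volume and a liver mask alone. It is aimed
at medical-physics and nuclear-medicine researchers working with
reconstructed emission volumes (NIfTI-1) and at anyone who needs a
reference implementation of threshold-sweep focus counting.

## The statistic

For a liver volume of interest (VOI) with maximum voxel value C_max, every
threshold C_thr maps to a threshold index

    ThI = (C_max − C_thr) / C_max  ∈ [0, 1).

At each of G thresholds (default 256), the number of uptake foci (NUF) —
disjoint connected components of above-threshold VOI voxels under 26-, 18-
or 6-connectivity — is counted and normalized by its maximum over the
sweep (nNUF). Tumour-free livers give a bell-shaped nNUF-vs-ThI curve;
tumours compress it towards higher ThI. The curve is summarized by the ThI
where the right branch crosses nNUF = 0.25, corrected for its dependence
on mean activity concentration m by a fitted quadratic f:

    nThI = ThI − f(m) + f(60),     m in counts/voxel.

nThI below 0.64 is a `low` band, 0.64–0.70 `indeterminate`, and 0.70 or
above a `high` band (strong indicator of tumour burden); per-patient
positive predictive values are computed against a tumour-free reference
pool with inclusive (≥) counting. A seeded digital liver phantom (Poisson
noise, Gaussian PSF, non-uniform uptake, optional hot lesions at a chosen
tumour-to-normal concentration ratio) makes the whole pipeline testable
without patient data.

## Worked example

Compare the bundled reference cohort — 13 livers that were negative at
imaging but radiologically confirmed within 3 years — against the
published tumour-free group summary, then band the patients:

```r
library(nnufti)

ref <- reference_cohort()
s   <- reference_summaries()$radtech_neg
group_compare(list(n = s$n, mean = s$mean, sd = s$sd), ref$nthi)
#> 	Pooled-variance two-sample Student t test
#>
#> data:  values_a and values_b
#> t = -2.9224, df = 51, p-value = 0.005166
#> sample estimates:
#> mean of x mean of y
#> 0.6230000 0.6584615

ref$band <- assign_band(ref$nthi)
head(ref[, c("patient_id", "nthi", "ppv", "band")], 5)
#>   patient_id  nthi ppv          band
#> 1        42F 0.748 1.0          high
#> 2        32F 0.743 1.0          high
#> 3        41F 0.718 1.0          high
#> 4        55F 0.697 1.0 indeterminate
#> 5        84M 0.659 0.5 indeterminate
```

The p-value (0.005) says the flagged cohort's nThI distribution is
genuinely shifted above the tumour-free mean 0.623; the four patients with
nThI above the tumour-free maximum 0.68 all have PPV 1.0.

Curves come from volumes: here a tumour-free phantom liver
(≈4,000 VOI voxels, mean 60 counts/voxel):

```r
ph <- generate_phantom(phantom_spec(shape = c(32, 32, 24),
                                    semi_axes_mm = c(55, 45, 35), seed = 7))
summary(nnufti(ph$volume, ph$voi, grid_size = 128))
#> nNUFTI curve summary
#>   Cmax:                 90.5365 counts/voxel
#>   mean concentration:   59.8934 counts/voxel
#>   threshold levels:     128
#>   max NUF:              37 (at ThI 0.2109)
#>   ThI at nNUF = 0.25:   right 0.3743, left 0.1074
```

The focus count peaks at 37 disjoint foci at ThI ≈ 0.21 and the right
branch falls through nNUF = 0.25 at ThI ≈ 0.37 — the number a lesion would
push upward. `plot()` on the curve object draws the bell curve;
`thi_at_nnuf()`, `fit_concentration_model()`, `normalize_thi()`,
`compute_ppv()` and `scan_optimal_nnuf()` expose every stage separately.

See the methods vignette (`vignettes/nnufti-method.Rmd`) for the model,
the phantom's design and its known fidelity limits.

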