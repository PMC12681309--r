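# utemap

Fast combined T1 and T2\* quantitative mapping for ultrashort echo time
(UTE) spoiled gradient echo MRI, in R.

Fast-relaxing musculoskeletal tissues (tendon, meniscus, ligament; T2\* ≈
1–20 ms) need UTE acquisitions to be seen at all, and conventional
relaxometry of them is prohibitively slow. `utemap` implements a two-scan
mapping framework — a low-flip UTE scan S1 with minimal T1 weighting plus a
dual-echo scan S2/S3 at the Ernst-angle condition — together with everything
needed to validate it end to end on simulated data. It is aimed at
quantitative-MRI methods developers and phantom/protocol designers.

## What it computes

All estimators derive from the spoiled gradient echo steady state

    S = S0 · sin(α) · (1 − e^(−TR/T1)) / (1 − e^(−TR/T1)·cos(α)) · e^(−TE/T2*)

* **Dual-echo T2\***: `T2* = (TE3 − TE2) / ln(S2/S3)` per voxel, with the
  later echo at an in-phase time (`inphase_echo_times()`: 2.46 / 4.92 ms at
  123.256 MHz, 3.3 ppm), plus a three-echo weighted log-linear fit as
  comparator (`map_t2star()`).
* **LUT T1**: the ratio S1/S2 at the shared ultrashort echo depends only on
  T1 and the effective flip angles; `build_lut()` tabulates it over
  1–4000 ms (1 ms steps) and `map_t1()` inverts each voxel's measured ratio
  through the table selected by its B1+-derived effective angle
  (per-degree bank, `build_lut_bank()`).
* **Reference estimators**: echo-train shifted multi-echo T2\* fits
  (`etsme_reference()`) and three-parameter magnitude inversion-recovery T1
  fits (`ir_fit()`).
* **Preprocessing**: background masking, B1+ resampling and polynomial
  smoothing, optional nonlocal-means denoising, S2−S3 subtraction images.
* **Protocol design**: T2\* sensitivity windows of an echo pair
  (`te3_sensitivity_window()`), Ernst angle (`ernst_angle()`), low-flip
  candidate admissibility (`fa1_tradeoff()`).
* **Digital phantoms + agreement statistics**: seeded multi-tube phantom
  simulation with Rician magnitude noise (`simulate_phantom_study()`),
  eroded cylindrical VOIs, and Bland–Altman limits of agreement
  (`bland_altman()`, differences as reference − mapping).

Volumes are NIfTI in and out (`read_volume()` / `write_volume()`); tabular
results are tibbles; report objects support `tidy()`, `glance()` and
`autoplot()`.

## Worked example

Simulate the seven-tube T2\* phantom at image SNR 50, map T2\* with the
dual-echo estimator at TE 0.03/2.46 ms, and compare tube VOI means against
the ground truth:

```r
library(utemap)

spec  <- default_t2star_phantom(snr = 50, seed = 7)   # tubes: 1..20 ms
study <- simulate_phantom_study(spec)
t2map <- map_t2star(study$s2_scan, "dual", te2 = 0.03, te3 = 2.46)

vois  <- tube_vois(study$truth, margin_voxels = 3)    # 2 VOIs per tube
stats <- voi_stats(t2map, vois)
stats
#> # A tibble: 14 × 7
#>   label        tube segment  mean     sd     cv n_valid
#>   <chr>       <dbl>   <int> <dbl>  <dbl>  <dbl>   <int>
#> 1 tube01_seg1     1       1  1.03 0.0974 0.0946     160
#> 2 tube01_seg2     1       2  1.01 0.0872 0.0867     160
#> 3 tube02_seg1     2       1  1.99 0.103  0.0519     155
#> 4 tube02_seg2     2       2  2.02 0.106  0.0527     155
#> # i 10 more rows

bland_altman(data.frame(reference = spec$tubes$t2star[stats$tube],
                        test      = stats$mean))
#> <agreement_report> n = 14 pairs
#>   mean difference -2.4% +/- 3.63% (SD)
#>   limits of agreement [-9.51, 4.72]%
```

The 1 ms tube sits at the edge of the estimator's sensitivity window for
this echo pair — `te3_sensitivity_window(0.03, c(2.46, 4.92))` gives usable
ranges of about 0.81–8.45 ms and 1.63–17 ms respectively — which is why the
short-spacing variant is the right choice for fast-relaxing tissue while
the 4.92 ms echo serves longer T2\*.

A command-line front end over the same functions ships at
`inst/cli/utemap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","utemap.R",package="utemap"))')" \
    simulate --phantom t2star --snr 50 --seed 7 --outdir sim
```

with subcommands `simulate`, `map-t2star`, `map-t1`, `build-lut`,
`preprocess`, `validate`, `design-protocol`.

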