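---
title: "Combined T1 and T2* mapping for UTE MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined T1 and T2* mapping for UTE MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utemap)
```

## The problem

Tissues with very short effective transverse relaxation times (tendon,
meniscus, ligament; T2* of roughly 1–20 ms) are invisible to conventional
echo times. Ultrashort echo time (UTE) sequences sample the signal tens of
microseconds after excitation and make these tissues quantifiable, but
conventional relaxometry — many echoes for T2*, many inversion times or flip
angles for T1 — is too slow for clinical use at submillimeter resolution.
`utemap` implements a two-scan protocol that yields both maps quickly:

* **Scan 1 (S1)**: one ultrashort echo at a low flip angle, minimizing T1
  weighting (defaults: TE 0.03 ms, TR 4.92 ms, FA 3°).
* **Scan 2 (S2/S3)**: a dual-echo scan at the Ernst-angle condition for
  T1 ≈ 500 ms (defaults: TEs 0.03/2.46/4.92 ms, TR 9.24 ms, FA 11°).

## Signal model

All estimators derive from the ideally spoiled gradient echo steady state,

$$S = S_0 \sin\alpha\,\frac{1 - e^{-TR/T_1}}{1 - e^{-TR/T_1}\cos\alpha}\,
  e^{-TE/T_2^*},$$

implemented in `spgr_signal()` and verified in the test suite against an
independent fixed-point Bloch iteration (RF tip, T1 relaxation over TR,
repeat to convergence; the iteration is run to a $10^{-12}$ fixed-point
tolerance, which takes a few hundred repetitions at TR/T1 ≈ 0.02 — a fixed
small iteration count would not reach the comparison tolerance).

**T2*** comes from the logarithmic two-echo ratio within scan 2,

$$T_2^* = \frac{TE_3 - TE_2}{\ln(S_2/S_3)},$$

(`dual_echo_t2star()`), with a three-echo weighted log-linear fit
(`map_t2star(..., "3te")`, weights $\propto S^2$) as the conventional
comparator. The later echo must be in-phase for water–fat voxels;
`inphase_echo_times()` computes the candidates from the scanner frequency
and a 3.3 ppm shift (2.46 and 4.92 ms at 123.256 MHz).

**T1** comes from the inter-scan ratio at the shared ultrashort echo. With
equal compared TEs, $S_0$ and T2* cancel:

$$\frac{S_1}{S_2} =
 \frac{\sin\alpha_1\,(1-e^{-TR_1/T_1})(1-e^{-TR_2/T_1}\cos\alpha_2)}
      {\sin\alpha_2\,(1-e^{-TR_2/T_1})(1-e^{-TR_1/T_1}\cos\alpha_1)}.$$

`build_lut()` tabulates this ratio over a discrete T1 grid (1–4000 ms in
1 ms steps by default) and `lut_invert()` maps measured ratios to the
nearest grid entry. The implementation enforces the equal-TE precondition —
`signal_ratio()` refuses protocol pairs whose compared echoes differ,
because T2* would then not cancel.

## B1+ correction

Flip angles in the ratio are effective, not nominal. `map_t1()` consumes a
relative transmit-field map (B1+; 1.0 = nominal), selects for every voxel
the lookup table whose integer effective second-scan angle is
`round(b1 * FA2)` from a per-degree table bank (`build_lut_bank()`), and
inverts the ratio there. Both scans share one transmit chain, so a single
scale multiplies both nominal angles; FA1 is scaled by the same factor
inside each table rather than rounded independently. Bank keys whose ratio
curve is not strictly monotone in T1 (this happens only above an effective
FA2 of ~132°, i.e. transmit scales above ~12× nominal) are dropped and
reported; `build_lut()` refuses non-monotone tables outright since their
inversion would be ambiguous.

Measured B1+ maps are low-resolution and noisy; the preprocessing chain
resamples them to the image grid (`resample_to_grid()`, trilinear,
center-aligned frames) and replaces them by a low-order polynomial fit
(`smooth_field()`, default total degree 3 on normalized coordinates — the
degree is a package choice; a transmit profile at 3 T is smooth and
quadratic-to-cubic structure captures it while suppressing noise).

## Reference estimators

* **ETsME T2*** (`etsme_reference()`): a mono-exponential fit over the
  echo-train shifted multi-echo sampling — 22 first echoes sliding over
  0.03–1.5 ms plus fixed echoes at 4.92/7.38/9.84/12.3 ms. The fit uses all
  26 unique echo times by default; `shifted_only = TRUE` restricts it to the
  sliding echoes. Including the fixed echoes anchors slow decays and is the
  default because the scheme acquires them anyway.
* **IR T1** (`ir_fit()`): three-parameter magnitude model
  $|A - B e^{-TI/T_1}|$ fitted by Levenberg–Marquardt from 16 log-spaced T1
  starts (10–8000 ms), lowest residual kept. The magnitude (not signed)
  model matches magnitude-image fitting; polarity restoration is not
  attempted. Degenerate series (flat signals, T1 at the search bound) are
  flagged rather than silently returned.

## Noise model and what it implies

The simulator adds Rician magnitude noise — two Gaussian channels,
$M = \sqrt{(\mu + g_1)^2 + g_2^2}$ — not additive Gaussian noise. This
matters: the Rician floor inflates weak late echoes, and the log-ratio
estimator turns that into a T2*-dependent bias. With the default protocols
at image SNR 50 (defined as the mean noiseless tube magnitude at the first
echo of the dual-echo scan over the channel SD), the TE3 = 4.92 ms variant
overestimates T2* = 1 ms by ~30% while the TE3 = 2.46 ms variant stays
within ~1%; at T2* = 2 ms and above both variants are within a few percent,
and for long T2* the longer echo spacing is the more precise one. The
`te3_sensitivity_window()` helper expresses the underlying trade-off in
closed form: a pair discriminates T2* well where the later echo has decayed
by at least 25% but still retains more than 5% of the earlier echo.

## The digital phantom

`default_t2star_phantom()` (7 tubes, T2* = 1/2/3/5/8/12/20 ms, common T1 of
1000 ms) and `default_t1_phantom()` (10 tubes, T1 = 300–1300 ms in even
steps, common T2* of 30 ms) emulate multi-tube agarose/carrageenan phantoms
on a 64×64×16 grid at 0.8 mm isotropic spacing, tubes arranged on a ring.
The per-tube relaxation times are package choices evenly covering the
stated ranges (a wet-chemistry phantom specifies concentrations, not
relaxation times). The default B1+ field is uniform (1.0), so that
noiseless end-to-end runs isolate the estimators' intrinsic error — pure
LUT-grid quantization for T1 (≤ 1 ms when the truth lies on integer
milliseconds, hence the integer tube T1 values), and floating-point-level
error for all three T2* estimators. A smooth transmit profile is available
via `quadratic_b1_field()` and `phantom_spec(b1_field = ...)`; with a
non-uniform field the integer-degree bank quantization adds a
rounding-of-effective-angle error of up to a few tens of ms at
mid-range T1, which is the accuracy the per-degree bank design itself
implies.

What the simulator does **not** emulate: k-space trajectories and their TE
variation across the spiral readout, chemical-shift (fat–water) phase
evolution between echoes in mixed voxels, motion, receive-field bias,
imperfect inversion in the IR reference (configurable efficiency, ideal by
default), and multi-compartment (bi-exponential) decay. Passing phantom
tests therefore validates the estimator mathematics and noise behavior, not
robustness to those acquisition effects.

## Validation statistics

`tube_vois()` erodes each tube in-plane by a 3-voxel disc margin, drops the
outermost slices, and splits the interior into two axial segments — two
VOIs per tube as the unit of analysis. `voi_stats()` reports mean, SD, CV
and valid-voxel counts over valid voxels only. `bland_altman()` computes
differences as *reference − test* (percent of reference by default) with
limits of agreement at exactly mean ± 1.96 SD. On the simulated noisy
phantoms (SNR 50) the LUT T1 map agrees with the IR reference within ~1%
mean difference, and the TE3 = 2.46 ms dual-echo variant shows a smaller
mean absolute percent difference against the ETsME reference over tubes
with T2* ≤ 11 ms than the TE3 = 4.92 ms variant — the ordering the
sensitivity-window analysis predicts. These numbers are recomputed by the
test suite and by `scripts/acceptance.R`.

## Numerical and design choices

* **Masking**: background threshold at a fraction (default 0.1) of the 99th
  percentile of valid voxels — robust to hot pixels; the threshold is
  exposed because no canonical value exists.
* **Invalid data**: invalid voxels are `NaN` on disk and an explicit mask in
  memory; every statistic excludes them. Non-positive magnitudes are
  invalidated, never clamped — clamping would fabricate long T2*.
* **LUT inversion**: nearest grid entry (reproducing discrete-LUT behavior),
  ties toward the smaller T1; out-of-range ratios clamp to the boundary T1
  and are flagged rather than invalidated, keeping maps visually complete.
  A linear-interpolation toggle exists for smoother maps.
* **T2* fitting**: weighted log-linear least squares — deterministic and
  failure-free for 3–26 points; the reference fit refines nonlinearly.
  Dual-echo estimates above `t2_cap` (default 100 ms) are clipped and
  flagged but kept, so region statistics may include or exclude them.
* **Denoising**: a simplified patchwise nonlocal-means filter (noise level
  auto-estimated from the background, bandwidth `strength * sigma`),
  optional and off by default in validation runs so estimator results stay
  deterministic. The mapping math, not the filter, is the package's
  contribution.
* **FA1 admissibility** (`fa1_tradeoff()`): a candidate is *too weak* when
  the range of S1 over the T1 grid falls below `noise_level * max(S2)`, and
  *degenerate* when S1 and S2 are indistinguishable within noise across the
  entire grid (ratio ≡ 1 within noise). A single crossing of the S1 and S2
  curves — which the default protocols exhibit near T1 ≈ 3000 ms for every
  candidate — is deliberately not flagged: the monotone ratio still
  discriminates there. With 2% noise this reproduces the narrative choice
  of 3°: 1° is too weakly weighted, 3° is admissible.
* **Coregistration** is out of scope (simulated volumes share a grid by
  construction); `check_alignment()` warns when a cross-correlation peak
  sits off-center by more than half a voxel.

## Problem sizes

Validation runs use 64×64×16 volumes (two default phantoms), 200-replicate
noise simulations at 200 voxels per replicate for the bias analysis, 26-echo
ETsME and 22-TI inversion-recovery series, and per-degree LUT banks built
over the effective angles the phantom fields actually reach. These sizes
were chosen so a full validation cycle completes in well under a minute on
one core while keeping Monte-Carlo standard errors far below the effect
sizes being asserted.

## Known limitations

Mono-exponential T2* masks multi-compartment decay in collagen-rich tissue;
neither dual-echo variant is reliable below T2* ≈ 1 ms where the signal has
essentially vanished by the first in-phase echo. LUT T1 accuracy degrades
when the measured ratio approaches the flat long-T1 end of the curve, and
the integer-degree B1 bank bounds achievable accuracy under strong transmit
inhomogeneity. The IR reference assumes ideal inversion, which real
short-T2* tissue violates.
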