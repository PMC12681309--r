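Package: utemap
Title: Fast Combined T1 and T2* Mapping for Ultrashort Echo Time MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative relaxometry toolkit for ultrashort echo time (UTE)
    spoiled gradient echo MRI of fast-relaxing tissue. Implements voxelwise
    dual-echo T2* estimation from the logarithmic echo ratio, three-echo
    mono-exponential fitting, and lookup-table (LUT) T1 estimation from the
    signal ratio of two differently T1-weighted UTE acquisitions with
    transmit-field (B1+) correction via per-degree LUT banks. Ships the
    matching reference estimators (echo-train shifted multi-echo T2* fits and
    three-parameter inversion-recovery T1 fits), a preprocessing chain
    (background masking, B1+ resampling and polynomial smoothing, nonlocal
    means denoising, subtraction images), protocol-design utilities (in-phase
    echo times, Ernst angle, echo-spacing sensitivity windows, low-flip-angle
    selection), a digital multi-tube phantom simulator with Rician magnitude
    noise, and Bland-Altman agreement statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    yaml,
    EBImage,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
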