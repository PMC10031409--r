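Package: mwstroke
Title: Microwave Brain-Stroke Detection with Sinc Wavelet-Matched Filter Banks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided detection and localization of a brain
    stroke from wideband microwave backscatter. Mono-static reflection
    coefficient sweeps from a hemi-elliptical array of antennas surrounding
    the head are transformed to the time domain, the dominant air-skull
    background reflection is removed by one of five subtraction approaches,
    and the residual target response is filtered through a bank of truncated
    sinc wavelet-matched filters. Detection and localization statistics
    include the relative wavelet energy scalogram, Shannon wavelet entropy in
    the scale and time domains, and the distance between wavelet energy
    distributions at symmetrically opposite antennas. A point-scatterer
    simulator of the measurement system is included so the full pipeline can
    be exercised without proprietary phantom data. Readers and writers for
    Touchstone .s1p and CSV sweep layouts are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
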