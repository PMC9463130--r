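Package: ctcm
Title: Analysis Tools for Biomimetic Cardiac Tissue Culture Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of ring-mounted beating heart-slice
    cultures stimulated by a pneumatic cardiac-cycle driver. Provides the
    device cardiac-cycle model (raised-cosine pressure waveform,
    threshold-triggered electrical stimulation scheduling, spherical-cap
    membrane geometry and percent-stretch calculations), a synthetic
    Lambertian video generator with full ground truth, a video-based
    tissue-movement quantification pipeline (masked intensity trace,
    zero-phase low-pass filtering, polynomial detrending, peak analysis and
    cycle metrics), and shape-from-shading regional strain estimation with
    stimulated-versus-unstimulated comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    png,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
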