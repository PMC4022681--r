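Package: rotaframe
Title: Spin-Lock T1rho Mapping of Knee Cartilage: Simulation, Calibration, Fitting and Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative spin-lattice relaxation mapping in the
    rotating frame (T1rho) of articular cartilage. Provides a rotating-frame
    Bloch simulator of B0/B1-compensated spin-lock preparation clusters, a
    synthetic multi-TSL knee phantom generator with field inhomogeneity and
    Rician noise, WASSR-based B0 mapping, double-angle B1 mapping, STEAM
    two-spectrum reference-voltage calibration, voxel-wise mono-exponential
    T1rho fitting with goodness-of-fit maps, morphological cartilage zone
    segmentation, and test-retest reliability statistics (ICC with confidence
    intervals, Pearson correlation, coefficient of variation, and SNR with
    Rician correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    jsonlite,
    minpack.lm,
    tibble,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
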