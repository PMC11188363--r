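Package: wsqeeg
Title: Quantitative Interictal EEG Biomarkers for West Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and group statistics for interictal scalp EEG
    in West syndrome and similar infantile epileptic encephalopathies. Computes
    Welch relative band power, wavelet-bicoherence cross-frequency coupling
    (FIWBIC), bi-channel magnitude-squared coherence, and four signal-complexity
    measures (approximate, sample, permutation and wavelet entropy) on
    19-channel 10-20 recordings, then screens features with two-sample t-tests
    under Benjamini-Hochberg false-discovery-rate control and relates them to
    structural and genetic etiology flags by multivariate linear regression.
    Includes a fully seeded synthetic EEG cohort generator with controllable
    band power, quadratic phase coupling, inter-channel connectivity and signal
    regularity, so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
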