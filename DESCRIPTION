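Package: repdyn
Title: Frequency Content and Representational Dynamics of Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the frequency content of stimulus-evoked
    neural responses to the temporal dynamics of decodable information in
    epoched electrophysiological (MEG/EEG-like) data. Provides a generative
    two-condition model of evoked responses with bandlimited Gaussian noise,
    closed-form and Monte-Carlo mutual-information timecourses for
    instantaneous, narrowband, and complex-spectrum decoding paradigms, the
    representational-aliasing arithmetic (information bandwidth doubling and
    Nyquist folding), short-time Fourier transform feature extraction,
    cross-validated decoding engines with accuracy-spectrum and
    cluster-based permutation statistics, and turn-key simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    arrow
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
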