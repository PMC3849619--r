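Package: gaborpursuit
Title: Multivariate Matching Pursuit in Metric-Optimal Gabor Dictionaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse greedy (matching pursuit) decomposition of single- and
    multi-channel, optionally multi-trial time series in Gabor dictionaries
    whose density is controlled by a single inner-product-metric parameter
    bounding the one-step decomposition error.  Implements the monochannel
    engine with product-update bookkeeping, windowed-FFT inner products and
    fast orthogonality screening, the multivariate variants MMP1/2/3 and
    their channel-by-trial compositions, time-frequency energy maps,
    parameter-based atom filtering with sleep-EEG presets (slow waves,
    spindles), raw-binary and text epoch formats, a structured text book
    format, a synthetic-signal generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
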