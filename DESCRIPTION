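Package: airwave
Title: Robust Gap Imputation and Wavelet Dissimilarity Analysis of Hourly
    Air-Quality Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hourly air-pollutant concentration series (PM2.5 and
    similar) with structured missing data. Cleans calendar-indexed hourly
    records, detects runs of consecutive missing hours, and imputes them with
    a run-length policy that combines interpolation with classical and robust
    location estimates (median, trimmed means, Andrews' wave) computed on
    eight calendar neighborhood sets drawn from five prior years. Imputation
    quality is evaluated by masking experiments (Pearson, Kendall, Spearman
    correlations and residual sum of squares). Complete units are summarized
    by 80-statistic signatures built from a five-level periodized Daubechies
    wavelet decomposition with cross-scale regression errors, and units are
    compared through PCA, classical and nonmetric multidimensional scaling
    and Hausdorff distances. Includes a synthetic generator of heavy-tailed
    hourly series with controlled MCAR/NMAR missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
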