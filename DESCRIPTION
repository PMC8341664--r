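Package: dpsample
Title: Distribution-Preserving Class-Proportional Downsampling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Optimal distribution-preserving downsampling of large numeric
    tabular data sets. Repeats seeded class-proportional uniform sampling over
    many trials, scores every candidate subset by the per-variable
    distributional distance between the subset and the full data
    (Anderson-Darling, Cramer-von Mises, Kolmogorov-Smirnov, Kuiper,
    Wasserstein and a variance-weighted ECDF distance on the raw values, plus
    Euclidean, symmetrised Kullback-Leibler and absolute mean relative
    difference on smoothed-data-histogram densities), and returns the subset
    minimising the maximum distance across variables. Representativeness is
    quantified as the mean squared error of reconstructing the unsampled
    remainder from a principal-component projection of the sample. Also
    provides exact counting of the class-proportional sampling space,
    synthetic Gaussian-mixture generators for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
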