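Package: pathtrace
Title: Reconstruct Pharmaceutical Distribution Paths from Dyadic Shipping Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs complete per-package distribution paths
    (manufacturer through distributors to final destination) from
    chronological dyadic shipping-transaction records, such as DEA ARCOS
    extracts, under an explicit stock-management policy (FIFO or LIFO).
    Provides batch-level allocation with prefix-shared path storage, a
    forward simulator of multi-echelon distribution with known ground-truth
    paths, and the validation statistics used to characterise reconstructed
    path sets: unique and weighted Jaccard similarity, path-length
    histograms, great-circle travel distances, days-in-transit
    distributions, and distributor entry/exit turnover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
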