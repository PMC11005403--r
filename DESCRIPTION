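Package: mfakit
Title: Marker Frequency Analysis of Replication Initiation in Archaea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify replication-origin (oriC) usage in polyploid
    archaea from deep-sequencing coverage. Implements marker frequency
    analysis (MFA): binning and mean-normalization of read depth over a
    circular chromosome, circular Gaussian smoothing, and detection and
    quantification (height, area) of the oriC peak across growth time
    courses. Includes a generative simulator of an asynchronous replicating
    cell population mixing origin firing with dispersed
    recombination-dependent initiation, together with its closed-form
    expected copy-number oracle; absolute qPCR quantification of chromosome
    copies per cell (standard curves, amplification efficiency, ploidy);
    doubling-time estimation from growth kinetics; and western-blot
    densitometry normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
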