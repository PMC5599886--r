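Package: buildprov
Title: Genome-Build Provenance for Genomic Track Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Establishes and repairs genome-build provenance for genomic
    track files (BED, GFF, WIG, narrowPeak, broadPeak). Predicts the
    genome build of orphan interval files from coordinate compatibility
    against a bundled, extensible chromosome-size registry; audits files
    for build tokens in filenames and header lines; injects build
    annotations as header comments, track-line attributes or filename
    tags; and quantifies cross-build coordinate incompatibility by 1-kb
    binning and chain-based lift-over with a minimum-match threshold.
    Includes deterministic synthetic-fixture generators for track and
    chain files and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
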