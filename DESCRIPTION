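Package: neuroburst
Title: Network Burst, Functional Connectivity and Calcium Transient
    Analysis for Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity of cultured neuronal
    networks recorded on 8x8 multielectrode arrays and by calcium imaging.
    Detects extracellular spikes with a median-normalized amplitude threshold,
    segments small network bursts from the total spiking rate, maps burst
    activation patterns, infers directed functional connectivity from
    delayed-synchronous spike pairs (with hub identification and hub-overlap
    statistics), and detects calcium transients from fluorescence traces by
    derivative thresholding. Includes a synthetic-data generator that plants
    spikes, network bursts, directed connections and calcium events with
    known ground truth, so that every stage of the pipeline can be validated
    by ground-truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
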