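Package: rnaseprotect
Title: In Silico DNA-Probe RNase Protection Assays for Capped mRNA
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Design and simulation toolkit for DNA-probe ribonuclease
    protection assays of in vitro transcribed mRNA.  Designs antisense DNA
    probes, simulates RNase A / RNase T1 digestion of single-stranded RNA
    regions while probe-hybridized regions remain protected under high
    salt, predicts denaturing urea-PAGE lanes including the RNA/DNA
    mobility offset and the 5'-cap (cap 0) mobility shift, quantifies
    capping efficiency from band intensities, computes theoretical
    oligoribonucleotide masses with correct end chemistries for RNase
    mass mapping, designs probe tilings that maximize mass-mapping
    sequence coverage, and implements a rule-based procedure that
    integrates in vitro transcription and Vaccinia capping reaction
    buffers into a single recipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    grDevices,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
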