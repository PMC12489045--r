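Package: drtkit
Title: Characterization of Protein-Primed Reverse Transcription Products,
    Oligomer Geometry, and ncRNA Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the outputs of defense-associated reverse
    transcriptase (DRT) systems that synthesize homopolymeric poly(dA) DNA.
    Provides read triage against reference sequences, poly-C terminal
    transferase tail trimming, homopolymer prevalence spectra, positional
    base composition, ambiguous-base counts-per-million, exact-identity read
    clustering and motif-discovery input preparation; quantification of
    inter-dimer-unit angles in oligomeric assemblies from atomic coordinates
    with tetramer-like versus hexamer-like classification; strand-aware
    upstream sequence extraction and alignment conservation profiling for
    non-coding RNA homolog families; and a synthetic-data module that
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
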