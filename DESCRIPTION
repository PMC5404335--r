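Package: sonifyDNA
Title: Sonification of DNA Sequences into MIDI Auditory Displays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts DNA sequences into auditory displays. Six sonification
    algorithms map mono-nucleotides, di-nucleotides (single frame or two
    staggered frames), codons (non-degenerate, degenerate by the genetic
    code, or all three reading frames at once) onto a six-note blues scale,
    with optional start/stop-codon gating of each reading frame and
    percussion highlighting of start and stop codons. Scores are written as
    standard MIDI files and as machine-readable note-event tables, and a
    fixture generator builds the classes of test sequences (homopolymers,
    tandem repeats with injected mutations, stop-codon constructs) needed to
    study the displays. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
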