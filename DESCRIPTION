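Package: primerwalk
Title: Batch Design of Boundary-Anchored PCR Primers with
    Nearest-Neighbour Melting Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs PCR primers for single-nucleotide-precision cloning in
    batches. Each amplicon's boundaries are fixed at the ends of its FASTA
    record, so the only design freedom is how far each primer walks into the
    template; the walker enumerates every boundary-anchored candidate,
    filters by a melting-temperature tolerance window, and ranks under an
    optional G/C 3'-end clamp before attaching user-supplied 5' extensions.
    Melting temperatures come from a nearest-neighbour thermodynamic engine
    with selectable parameter tables (SantaLucia 1998 unified or Breslauer
    1986), an entropic salt correction on a monovalent-equivalent cation
    concentration, and three formulations of the duplex equilibrium
    constant, including the excess-primer regime relevant to the first PCR
    cycles. Includes polymerase-buffer presets, FASTA/CSV input and output,
    a regression harness for validating predicted against experimental
    melting temperatures, and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
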