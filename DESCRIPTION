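Package: mitocomp
Title: Comparative Analytics for Annotated Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Mitocomp", "Developers", role = c("aut", "cre"),
    email = "mitocomp@example.org")
Description: Tools for comparative mitogenomics of vertebrate (especially
    teleost) mitochondrial genomes: base composition and AT/GC skew per
    region class, codon usage and RSCU under the vertebrate mitochondrial
    code, intergenic spacer and gene-overlap accounting on the circle,
    control-region tandem-repeat detection with fractional copy numbers,
    gene-order extraction with breakpoint distances and a duplication
    census, plus a fully seeded synthetic-mitogenome generator that emits
    GenBank/FASTA/feature tables together with machine-readable ground
    truth for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
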