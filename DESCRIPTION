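Package: dnashift
Title: Constraint-Satisfying DNA Storage Codec for Chinese Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes text (notably Chinese, via a fixed-length GB2312-derived
    character-to-nucleotide code table) into DNA sequences that satisfy
    synthesis constraints (GC content 40-60 percent, homopolymer runs of at
    most three), using a deterministic cumulative base-substitution ("DNA
    shift") transform with a (mod, iterate) parameter search, systematic
    Reed-Solomon error correction over GF(256), and record framing with
    address indices. Includes a substitution-error channel simulator, seeded
    synthetic-text generation, FASTA import and export of encoded records,
    and full round-trip decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
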