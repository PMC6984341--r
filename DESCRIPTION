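Package: mitochar
Title: Characterization Statistics for Scleractinian Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation-level characterization of circular coral
    mitochondrial genomes: GenBank and tabular feature I/O with circular,
    segmented coordinates; base composition and AT/GC skew statistics for
    whole genomes, gene classes and codon positions; codon usage and
    relative synonymous codon usage (RSCU) under the coelenterate
    mitochondrial genetic code; pairwise Ka/Ks per gene by the
    Nei-Gojobori (1986) counting method with Jukes-Cantor correction;
    per-gene architecture summaries including signed intergenic spacers;
    concatenated 13-gene supermatrix construction with neighbor-joining
    sanity trees; and a seeded synthetic mitogenome generator emulating
    the scleractinian gene arrangement (single-strand coding, group-I-type
    ND5 intron) so the full pipeline is testable without sequence
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
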