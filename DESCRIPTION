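Package: notocraft
Title: Assembly Curation, Conserved Synteny and Repeat Landscape Tools for
    Notothenioid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages used to build and curate a chromosome-level
    notothenioid fish genome, exercised end-to-end on a seeded synthetic-genome
    generator. Includes long-read subsampling and overlap-based chimera
    scrubbing, assembly contiguity and completeness summaries (N50/L50, BUSCO
    percentages), conversion of Hi-C scaffolding maps (3d-DNA '.assembly'
    dialect) to AGP with FASTA reconstruction, curation edits with annotation
    coordinate liftover, reciprocal-best-hit conserved-synteny clustering with
    fusion/inversion/translocation detection, windowed gene and repeat density
    tracks, Kimura 2-parameter repeat landscapes, k-mer clump locus detection,
    gene-integrity (pseudogene) checks, and supermatrix concatenation
    utilities for phylogenomics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
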