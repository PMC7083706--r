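Package: ssrpanel
Title: Development of Multiplex SSR-PCR Assay Panels from Population
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to develop multiplex SSR-PCR (microsatellite) assays
    from a reference genome and population genotype data. The package
    catalogs perfect tandem repeats under the rotation/reverse-complement
    motif canonicalization, genotypes repeat tract lengths from spanning
    reads, profiles genotyping and allelotyping error in full-sib families
    with a length-deviation score, assesses saturation of allele number
    and allele length range by rarefaction over individuals (with Friedman
    and Nemenyi tests), selects highly polymorphic loci, designs
    variant-masked locus-specific primer pairs checked by in-silico PCR,
    and packs compatible primer pairs into fluorochrome-labeled multiplex
    groups. A self-contained simulator generates planted-SSR genomes,
    Mendelian families with controllable stutter error, and spanning
    reads, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
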