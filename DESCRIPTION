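Package: AllelicReq
Title: Allelic Requirement, Inheritance and Variant Consequence Terminology
    for Mendelian Disease-Gene Curation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Machine-readable harmonized terminology for Mendelian
    disease-gene relationships: the eight allelic-requirement /
    mode-of-inheritance term pairs with their HPO identifiers, cross-cutting
    inheritance qualifiers, and the Sequence Ontology hierarchy of
    disease-associated variant consequences. Bundles an ordinal likelihood
    matrix linking SO variant classes to six high-level consequence terms,
    classifies variants on transcript models from first principles including
    nonsense-mediated-decay (NMD) competence of premature termination codons,
    validates gene-disease curation records, and decides whether the variants
    observed in an individual satisfy a curated allelic requirement
    (zygosity-, phase-, karyotype- and pseudoautosomal-region-aware).
    Includes deterministic generators for toy transcripts and recipe-driven
    variant sets so the whole stack is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: VariantAnnotation, GenomicVariation, Annotation, Software
RoxygenNote: 7.3.3
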