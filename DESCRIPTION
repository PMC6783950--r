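Package: virocomp
Title: Comparative Genomics of Closely Related Virus Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing deep-sequenced isolates of large DNA
    viruses against an annotated circular reference genome. Implements
    transition:transversion-weighted counting estimators of dN/dS and of
    the intergenic-to-synonymous rate ratio dI/dS, genome-wide and per
    gene; strand-aware classification of fixed and polymorphic variants
    on circular genomes; shared/unique partitioning of variants between
    isolates; large-deletion mapping from per-position depth profiles
    with soft-clip breakpoint refinement and from k-mer anchor chaining
    of consensus assemblies; rule-based curation of within-isolate
    polymorphisms; pairwise genome comparison metrics and in-silico
    restriction-profile prediction; and a seeded synthetic-data
    generator that emulates read-mapping outputs for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
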