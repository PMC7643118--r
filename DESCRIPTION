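Package: hrdforest
Title: Mutational-Scar Classification of Homologous Recombination Deficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pan-cancer detection of homologous recombination deficiency (HRD)
    from whole-genome somatic mutation catalogs. Classifies SNVs into 96
    trinucleotide contexts, indels by flanking microhomology / tandem-repeat
    context, and structural variants by type and length; collapses the
    resulting profiles into 29 relative-contribution features; and trains a
    three-class random forest (BRCA1-deficient, BRCA2-deficient, proficient)
    with rank-based feature selection, class resampling chosen by
    cross-validated grid search, and repeated nested-CV blacklisting of
    inconsistently labeled samples. Also scores biallelic gene inactivation
    from copy-number segments and annotated variants (LOH, deep deletion,
    pathogenicity P-scores), tests gene-deficiency enrichment in
    HRD-classified cohorts, and ships a synthetic-fixture generator
    (genomes, VCFs with planted mutation contexts, copy-number events,
    labeled cohorts) so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    pracma,
    Biostrings,
    Rsamtools,
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
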