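Package: ystrpop
Title: Forensic Y-STR Population Genetics: Diversity Statistics, AMOVA-Rst,
    Ordination, Phylogeny and Haplogroup Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal short tandem repeat (Y-STR)
    haplotype data: a lossless haplotype-table data model supporting
    multi-copy loci and microvariant alleles, forensic summary statistics
    (allele and allelic-combination frequencies by direct counting, Nei's
    unbiased gene diversity, haplotype diversity, discrimination capacity),
    single-level AMOVA on repeat scores with pairwise Rst and permutation
    p-values, classical multidimensional scaling, principal component
    analysis of haplogroup frequency tables, neighbor-joining trees with
    Newick export, nearest-neighbor Y-haplogroup prediction against labeled
    reference panels, and a forward stepwise-mutation-model simulator with
    closed-form distance expectations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
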