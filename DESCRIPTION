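Package: haploweb
Title: Species Delimitation with Haplowebs and Bipartition Congruence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits species from co-dominant nuclear sequence markers
    using haplowebs: haplotype networks augmented with links between
    alleles found co-occurring in heterozygous individuals. Connected
    allele pools define single-locus fields for recombination (sl-FFRs,
    groups of individuals that share no allele with any other group);
    haploid markers are sorted into haplogroups. Agreement between
    markers is quantified by enumerating the bipartitions of the sample
    set each marker supports and scoring every bipartition by the
    percentage of independent datasets supporting it, with partition
    join (multilocus FFRs), meet (common refinement) and a threshold
    reconciliation yielding the final putative species. Includes
    median-joining and minimum-spanning haplotype network construction,
    readers for phased-allele FASTA and genotype tables, a population
    simulator with known species truth (including F1 hybrids,
    introgression and shared ancestral haplotypes), GraphML/DOT/SVG
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
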