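Package: dropstrain
Title: Droplet-Based Single-Cell Cultivation Design and Strain-Level
    Metagenomic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing droplet-microfluidic
    cultivation experiments on complex microbial communities such as the
    honeybee gut microbiota. Implements Poisson single-cell encapsulation
    statistics (occupancy probabilities, required cell densities for a
    target loading rate), a mechanistic simulator of competition-free
    droplet cultivation versus shared-resource bulk culture over
    strain-structured communities, species-level community profiling from
    marker-gene counts (relative abundance, alpha and beta diversity,
    principal coordinate analysis), strain-level single-nucleotide-variant
    profiling from per-site allele-count pileups (bi-allelic and
    prevalence filtering, coding SNV fractions, shared-polymorphism
    Jaccard distances), and comparative genomics (fragment-based average
    nucleotide identity, tetranucleotide z-score signatures, reciprocal
    ortholog clustering with core-genome fractions, neighbour-joining
    trees).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    deSolve,
    igraph,
    jsonlite,
    ape,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
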