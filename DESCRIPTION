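Package: phylogsm
Title: Expected Genetic Similarity Matrices from Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the expected genetic similarity matrix (GSM) of a set
    of taxa directly from a phylogenetic tree under the infinite sites
    mutation model, by summing standardized allele indicators over the
    bipartitions induced by the tree's edges, weighted by relative branch
    length.  Also provides the empirical GSM from binary haploid genotype
    matrices, two comparator tree kernels (Gaussian patristic-distance
    similarity and shared root-path similarity), a Kingman coalescent /
    infinite-sites simulator for validation, a Gibbs-sampled
    variance-component linear mixed model for narrow-sense heritability,
    and drivers for consistency and comparison studies including
    summarisation of GSM uncertainty over posterior tree ensembles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils, graphics
Suggests: testthat (>= 3.0.0), phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
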