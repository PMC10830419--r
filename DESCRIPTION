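Package: mitoscan
Title: Mapping and Modelling Mitonuclear Hybrid Incompatibilities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and quantifying mitonuclear hybrid
    incompatibilities from local-ancestry data in hybrid crosses and natural
    hybrid populations. Provides forward-in-time simulators of F2 intercrosses
    and multigeneration hybrid swarms under mitonuclear viability selection,
    segregation-distortion scans with genome-wide quantile envelopes,
    rejection approximate Bayesian computation for selection and dominance
    coefficients, partial-correlation admixture mapping with simulated
    genome-wide significance thresholds, permutation tests for epistatic
    survival effects, simulation tests of mitochondrial introgression versus
    incomplete lineage sorting, codon-level (NG86) substitution counting with
    parsimony polarization onto branches, and residue contact classification
    between interacting proteins across structural model replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    KernSmooth,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, PopulationGenetics, Epistasis, Software
Collate: 
    'mitoscan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'distortion.R'
    'abc.R'
    'admixture.R'
    'ancestry-io.R'
    'codon-utils.R'
    'codon-sim.R'
    'contacts.R'
    'dnds.R'
    'epistasis.R'
    'introgression.R'
    'pipeline.R'
    'simulate.R'
    'toy-structure.R'
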