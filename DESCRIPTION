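Package: oligostate
Title: Oligomeric-State Analysis of Self-Associating Proteins by
    Light Scattering, SAXS and Coarse-Grained Helix Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the oligomeric state of self-associating
    proteins such as Survival Motor Neuron (SMN) and for discriminating
    parallel from antiparallel dimer-of-dimers assemblies.  Implements
    glycine/YG-zipper motif scanning and cross-species residue mapping,
    Debye-plot molar-mass determination from multi-angle light-scattering
    chromatograms, small-angle X-ray scattering analysis (Debye-sum
    profiles, Guinier fits, regularized P(r) inversion with Dmax scanning,
    the parallel-axis-theorem inter-body distance, and SVD/EFA
    deconvolution of SEC-SAXS frame stacks), parametric coarse-grained
    helix-bundle models of dimers and tetramers with disulfide-crosslink
    propensity scoring, mass-action models of the dimer-tetramer-octamer
    ladder with temperature-dependent hydrophobic energetics, and
    generators for matched synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
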