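Package: rnadca
Title: Nucleotide Coevolution Analysis for RNA Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers direct nucleotide-nucleotide couplings from RNA multiple
    sequence alignments with mean-field Direct-Coupling Analysis (a pairwise
    Potts model), alongside mutual-information baselines with and without the
    average product correction. Coupling scores drive secondary structure
    prediction through a covariance-scored Nussinov dynamic program, and
    tertiary contact ranking with a sliding-window binomial enrichment
    statistic. Predicted contacts can be exported as flat-bottom distance
    restraints for molecular modelling. Includes readers and writers for
    Stockholm, aligned FASTA, dot-bracket, CT and PDB coordinate files, and a
    Gibbs sampler that generates synthetic alignments with planted secondary
    and tertiary couplings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
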