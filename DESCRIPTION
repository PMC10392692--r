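Package: saltsyn
Title: Salt-Dependent Aggregation Kinetics and Constant-pH Monte Carlo
    Simulation of alpha-Synuclein
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the anomalous salt dependence of
    alpha-synuclein amyloid formation at mildly acidic pH. Implements the
    seeded aggregation-kinetics model with secondary nucleation and
    elongation (moment equations, exact integrated rate law and the
    generalized-logistic approximation), normalisation and global fitting
    of thioflavin-T plate-reader traces to recover the rate-constant
    product k2*k+ per salt concentration, Henderson-Hasselbalch sequence
    titration (net charge, isoelectric point, region charges), a
    constant-pH coarse-grained Metropolis Monte Carlo engine for a free
    monomer above a surface-grafted layer of C-terminal tails in a slit
    (Debye-Hueckel screened electrostatics, Lennard-Jones excluded volume,
    harmonic bonds, titration swap moves), the derived observables
    (mass-centre density g(z), dipole-orientation profiles, average net
    charges), and a synthetic-data generator producing plate, metadata
    and truth tables with the statistical structure of the assay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    seqinr,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
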