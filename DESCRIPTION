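Package: toxdock
Title: Rigid-Body Toxin-Channel Docking Analysis with Empirical Scoring,
    Residue Contact Scores and Interface Surface Metrics
Version: 0.1.0
Authors@R:
    person("toxdock", "developers", email = "toxdock@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse rigid-body complexes of peptide toxins with
    large membrane receptors such as voltage-gated sodium channels. Reads
    standard PDB files (including multi-model NMR ensembles and HETATM
    glycans), assigns physical atom types, scores ligand poses with a
    five-term empirical function (two attractive Gaussians, steric
    repulsion, hydrophobic and hydrogen-bond ramps) and decomposes the
    score per residue, performs a seeded Monte-Carlo rigid pose search
    with RMSD clustering, computes residue-residue contact scores (RRCS)
    with amino-acid/glycan/region aggregates, detects hydrogen bonds,
    salt bridges, pi-cation and hydrophobic contacts, and measures
    Shrake-Rupley solvent-accessible and buried surface areas with
    interface percentage metrics. A synthetic-complex generator with
    machine-readable ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
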