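Package: mdfluct
Title: Comparative Residue-Fluctuation Analysis of Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing the structural rigidity of homologous
    proteins from molecular dynamics trajectories, built around the
    workflow used to rationalise enzyme thermostability: multi-model PDB
    and FASTA input, Kabsch superposition with per-frame RMSD and
    per-residue RMSF, cross-homolog residue mapping through a progressive
    global sequence alignment, detection of contiguous regions whose
    mesophile-minus-thermophile RMSF difference exceeds the average
    difference, and salt-bridge / hydrogen-bond distance series with
    occupancy classification. Includes a synthetic-trajectory generator
    with planted per-residue fluctuation amplitudes and planted two-state
    contacts for validation, and a config-driven pipeline over the whole
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
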