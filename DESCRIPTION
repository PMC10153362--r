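Package: specpair
Title: Design and Spectroscopy of Chlorophyll Special-Pair Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational machinery for de novo chlorophyll "special pair"
    protein design and characterization. Enumerates C2-symmetric
    histidine-chlorin dimer motifs from internal-coordinate grids (NeRF
    building), hashes the 6-D rigid transform between the ligating histidine
    backbone frames into a multi-value lookup table, and scans C2-homodimeric
    scaffolds for cross-chain residue pairs that can host a motif. Includes a
    48-atom tetrapyrrole structural-comparison convention, a coupled-oscillator
    exciton model for dimer absorbance and circular-dichroism spectra,
    sequential two-site binding-titration simulation and fitting,
    fluorescence-lifetime energy-transfer arithmetic, and a simplified
    two-component octahedral nanocage assembler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
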