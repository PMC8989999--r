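Package: acidhet
Title: Single-Cell Heterogeneity and Homolog Co-Occurrence Analysis of
    Bacterial Acid-Resistance Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for quantifying phenotypic heterogeneity of
    the three inducible acid-resistance systems of Escherichia coli (Gad,
    Adi, Cad) from three-colour fluorescence reporter data: per-field
    background subtraction, GFP-from-CFP spectral crosstalk correction,
    fluorophore-brightness normalization, the log-transform noise statistic
    (sd/mean of log(x+1)), ON/OFF calling, Pearson correlations and
    chi-square histogram comparisons. Also implements the comparative
    genomics side: BLAST-hit filtering, presence/absence co-occurrence
    matrices, Jukes-Cantor corrected distances, neighbor-joining trees with
    column-resampling bootstrap, and Newick export. A synthetic-data
    generator (correlated three-channel cell populations, rod-cell
    micrographs, presence tables, sequence evolution along a known tree)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    EBImage,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
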