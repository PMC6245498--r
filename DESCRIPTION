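Package: arassoc
Title: Discovery and Disentanglement of Aligned Residue Associations in
    Aligned Pattern Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical analysis of aligned pattern clusters (APCs) from
    protein families. Scores co-occurrences between aligned residues (or
    residue physicochemical properties) at different alignment sites with
    contingency-table adjusted standardized residuals, organises them into
    a statistical-residual vector space (SRV), and disentangles
    associations belonging to different classes or subgroups by principal
    component decomposition of the SRV followed by per-component
    re-projection.  Includes mixed-mode (categorical plus numeric)
    discretization, residue-to-property expansion with a built-in
    physicochemical property table, an address table mapping events back
    to sequences and sites, a seeded synthetic-data generator with
    exported ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
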