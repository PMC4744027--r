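Package: barcodeMOTU
Title: DNA Barcode Species Delimitation and Diversity Estimation for
    Hyperdiverse Insect Communities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to delimit species-like units (MOTUs) from COI barcode
    alignments by statistical-parsimony networks, pairwise-distance threshold
    clustering, single-threshold GMYC modelling and Poisson tree processes
    (PTP), to compare the resulting partitions with parataxonomic
    morphospecies (split/lump/perfect-match accounting), and to carry the
    delimitations into incidence-based species-richness estimation (Chao2,
    first- and second-order jackknife), sample-based accumulation curves,
    resampling standardization and elevational turnover. A synthetic-data
    generator produces communities, genealogies, JC69 alignments and
    error-perturbed morphospecies labels with known ground truth so the whole
    pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
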