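Package: siteburden
Title: Mutation Burden Testing in Protein Ligand-Binding Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps somatic coding mutations from tumour cohorts onto protein
    sequences, transfers ligand-binding-site annotations from solved
    protein-ligand structures by homology, weights binding residues by the
    fraction of their heavy atoms in contact with the ligand, and flags genes
    whose binding sites carry a statistically enriched mutation burden using a
    permutation null and Benjamini-Hochberg false discovery rates. Also
    provides cohort-level hypergeometric and binomial burden tests, enrichment
    curves against curated cancer-gene lists, and a deterministic synthetic
    fixture generator (genome, transcripts, structures, homology files,
    mutation cohorts) with planted binding-site enrichment for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
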