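Package: basementvirome
Title: Characterizing a Subseafloor Basement-Fluid Virome from Metagenome
    Scaffolds and Fluid Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference tools for characterizing the virome of geothermally
    heated oceanic-basement fluids sampled through borehole observatories.
    Implements rank-consensus taxonomic assignment of viral scaffolds from
    protein-homology hits, bin-first host inference with domain-level
    consensus fallback, depth-weighted host-fraction summaries, eligibility
    filtered classification of CRISPR-bearing scaffolds, a two end-member
    magnesium mixing model for fluid-sample purity, and epifluorescence
    count statistics. A seeded synthetic-community generator with planted
    ground truth makes every pipeline stage testable without access to the
    original metagenome assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
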