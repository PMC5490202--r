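Package: cladecons
Title: Clade-Aware Conservation Analysis of Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for clade-aware conservation profiling of protein
    families from multiple sequence alignments, built around the
    D14/KAI2 alpha/beta-hydrolase family of strigolactone and karrikin
    receptors. Extracts a core set of alignment columns under an
    occupancy threshold and establishes a unified residue numbering;
    computes per-position amino-acid frequency profiles within
    arbitrary clade subsets and classifies positions into cumulative
    conservation tiers (conserved, well conserved, highly conserved,
    invariant); discovers clade-characteristic residue sets and scores
    individual sequences against them; assesses conservation of named
    residue sets (such as the MAX2 interaction interface) clade by
    clade; constructs pruned and clade-jackknifed alignment datasets
    for downstream tree inference; and simulates clade-structured
    alignments with planted conservation structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
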