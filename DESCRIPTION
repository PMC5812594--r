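Package: sahscan
Title: Prediction and Analysis of Stable Single Alpha-Helix (SAH) Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts stable single alpha-helix (SAH) domains in protein
    sequences from helical-net interaction scoring. Every sequence is treated
    as a continuous right-handed alpha-helix; stabilizing and destabilizing
    side-chain interactions in i,i+3 and i,i+4 spacings, read from
    customizable scoring matrices, plus charged and hydrophobic interaction
    networks are summed over sliding windows (14, 21, 28 and 49 residues by
    default) and normalized so that a perfect EEEEKKK repeat scores 1.
    Per-residue score profiles are segmented into SAH-domains with a
    gap-tolerant merge rule and ranked by a length-independent
    SAH-domain-score. Includes dataset-level analytics (residue composition,
    heptad-frequency ranking, length distributions, multi-domain counts and
    unique-domain comparison across alternative transcripts), a persistent
    result store separating prediction from re-analysis, synthetic fixture
    generation, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
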