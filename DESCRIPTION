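Package: mipd
Title: Mirror-Image Phage Display Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for mirror-image phage display screens of
    stapled-peptide libraries. Decodes per-well NGS reads into a peptide-by-
    sample count matrix (quality trimming, flank location, trimer-codon
    translation, library-design filtering), computes spike-in-normalized
    abundances and the Hit Strength fold-change statistic with a 0.5
    pseudocount for zero blank counts, gates hits on dose-response across a
    bait concentration series, clusters hits into binder families with
    consensus sequences and position-frequency logo matrices, and converts
    selected L-peptide hits into mirrored D-peptide synthesis candidates.
    Includes a seeded synthetic-screen generator (log-normal background,
    planted binder families enriched by Langmuir occupancy, spike-in reads)
    and small structural utilities for reflecting coordinate models and
    classifying alpha-helix handedness from alpha-carbon virtual torsions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
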