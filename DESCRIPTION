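Package: betalayer
Title: Detection and Analysis of Beta-Layers in Trimeric Coiled Coils
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering and characterizing beta-layers, a
    triangular cross-chain supersecondary element found inside trimeric
    alpha-helical coiled coils. Implements a two-step structural search
    (Ramachandran-box sliding-window torsion patterns followed by
    cross-chain backbone hydrogen-bond tests within a biological
    assembly), TWISTER-style local periodicity and Crick-angle analysis
    with heptad register assignment, the periodicity algebra of residue
    insertions into heptad repeats, consensus sequence-motif scanning,
    and a generator of synthetic Crick-parameterized coiled-coil
    backbones with planted beta-layer fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
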