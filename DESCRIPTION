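Package: protophys
Title: Patch-Clamp Gating, Expression Filtering and Ratiometric Imaging for
    Leaf Protoplasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing membrane-transport physiology between leaf
    cell types (bundle-sheath versus mesophyll protoplasts). Implements
    whole-cell voltage-clamp analysis (ramp-slope conductance extraction,
    Boltzmann conductance-voltage fitting, open-probability and
    reversal-potential estimation, Nernst potentials, liquid-junction-potential
    correction), two-group log2 expression filtering (fold-change and P-value
    cutoffs, Venn summaries, transporter classification by expression level,
    hypergeometric category enrichment), and dual-excitation ratiometric
    membrane-potential image analysis (ring segmentation,
    background-subtracted excitation ratios, group comparison). A synthetic
    data module generates voltage-clamp recordings, spiked expression
    matrices, and ratio image pairs with known ground truth so every stage of
    the pipeline can be validated in a closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
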