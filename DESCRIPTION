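Package: lcnet
Title: Leaf Counting in Top-Down Rosette Plant Images with Convolutional
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Counts the leaves of rosette plants (Arabidopsis-like,
    imaged top-down) from RGB images. Provides a SegNet-style
    encoder-decoder that segments leaf pixels, a normalization layer that
    zeroes sub-threshold mask probabilities, and an LC-Net-style counting
    network that regresses the leaf count from the RGB image concatenated
    with its leaf mask, trained with a smooth L1 loss. Includes the
    standard counting metrics (DiC, absolute DiC, MSE, R-squared,
    percentage agreement) and segmentation metrics (pixel accuracy, IoU,
    Dice), a manifest-based data pipeline with bilinear resizing,
    flip/rotation augmentation and seeded train/validation/test splits,
    and a procedural rosette-image simulator that produces paired images,
    per-pixel leaf masks and exact counts so the full pipeline can be
    trained and evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
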