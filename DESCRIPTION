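Package: scratchdetect
Title: Automated Detection of Mouse Scratching Behaviour from Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects scratching bouts of laboratory mice in top-down arena
    video. Consecutive frames are differenced, cropped around the animal and
    binarized into motion images; sliding 21-frame segments are classified by
    a convolutional recurrent network (shared convolutional encoder, stacked
    LSTM, dense head) trained with class-imbalance-aware upsampling and
    flip/rotation augmentation. Per-segment probabilities are thresholded
    into scratch tracks, from which events, durations, confusion metrics and
    a three-way error taxonomy (boundary, false detection, oversight) are
    derived. Includes a synthetic labelled-video generator for end-to-end
    testing without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
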