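Package: dadpc
Title: Domain-Adaptive Deep Possibilistic Clustering for Multi-Subject Feature Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Robust unsupervised domain adaptation for multi-subject feature
    matrices such as EEG differential-entropy features. Jointly trains an
    encoder-decoder feature learner with a fuzzy-entropy-regularized
    possibilistic clustering objective under an adaptive sigma-norm robust
    loss, using a memory bank of unit-normalized features for nearest-centroid
    pseudo-labeling. Includes the iteratively reweighted solver for the
    adaptive loss family, differential-entropy feature extraction from
    band-filtered multichannel recordings, synthetic multi-subject data
    generators with controllable domain shift, outliers and label noise, and
    leave-one-subject-out evaluation protocols with a mutual-information
    feature map.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
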