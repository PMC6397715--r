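Package: mrnet
Title: Multi-Resolution Networks with Cumulative Lateral Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised hierarchical filter-bank networks in which a
    cumulative lateral-inhibition weight update forces the rows of each
    layer's filter bank onto a coarse-to-fine gradient, modelling the
    development of visual acuity and multi-resolution representation in
    the mammalian visual cortex. Provides the single-layer anti-Hebbian
    update (a masked generalisation of Sanger's rule), dilated
    sliding-window patch gathering and its overlap-summing inverse,
    stacked bottom-up forward passes, cascaded top-down image
    regeneration, a layer-wise training schedule with a smoothed
    stopping criterion, seeded synthetic image streams (pink noise,
    gratings, Gaussian blob scenes), and spectral analyses of the
    learned receptive fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
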