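Package: gafstress
Title: Mental-Stress Classification from Wearable Sensors via Gramian
    Angular Field Images and a Small Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies mental-stress states from multichannel wearable
    biosignals (chest accelerometer, ECG, EMG, EDA, temperature,
    respiration, or tabular stress-study features). Each multichannel
    sample is quantile-normalized within its class window and encoded as
    a Gramian Angular Field image whose pixels are pairwise angular
    sums of the rescaled channel values; the images are classified by a
    small convolutional network (three 3x3 convolutions with batch
    normalization, max pooling, and two dense layers) trained with Adam
    on categorical cross-entropy. Includes a synthetic multichannel
    generator for end-to-end testing, per-class precision/recall/F1
    reporting with confusion matrices, and loaders for per-subject
    chest records and delimited feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
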