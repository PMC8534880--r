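Package: dcra
Title: Deep Coupling Recurrent Auto-Encoders for Multimodal Vigilance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates driver vigilance (PERCLOS, the percentage of eye
    closure) from two physiological feature streams, such as EEG and EOG
    band-power features, by fusing them with a deep coupling recurrent
    auto-encoder (DCRA). Two stacked gated-recurrent-unit (GRU)
    auto-encoders, one per modality, are tied at a low-dimensional coupling
    layer by a joint loss whose cross-modal term is a squared Mahalanobis
    distance learned beforehand by probabilistic global distance metric
    learning (PGDM). Includes a synthetic multimodal session generator
    driven by a latent vigilance process, layer-wise pretraining and Adam
    fine-tuning implemented from first principles, a linear PERCLOS
    regression head, five-fold cross-validation with RMSE and Pearson
    correlation, and Friedman/Nemenyi machinery for comparing estimators
    across datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
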