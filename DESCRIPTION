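Package: msprompt
Title: Soft Prompt-Tuning for Few-Shot Short-Text Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cloze-style few-shot classification of short (especially
    biomedical) texts with a frozen masked language model. Trainable
    continuous prompt tokens are re-encoded by a BiLSTM and assembled
    around the input and a mask slot; the verbalizer (the class to
    label-word mapping) is built automatically from a knowledge base of
    entity-concept membership probabilities and from windowed
    pseudo-log-likelihood scoring under the masked language model.
    Includes a tiny trainable reference masked language model, synthetic
    data generators that emulate class-conditional short-text corpora,
    and a K-shot episode evaluation harness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
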