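Package: bioner
Title: Biomedical Named Entity Recognition with a Character-Attentive
    BiLSTM-CRF Tagger
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence labeling for biomedical named entity recognition
    (genes, proteins, DNA/RNA, cell lines and cell types). Implements a
    bidirectional LSTM encoder over attention-composed character
    representations and pre-trained word embeddings, with a linear-chain
    conditional random field output layer, trained by online AdaGrad with
    hand-derived analytic gradients. Every architectural component is
    switchable (CRF versus per-token softmax decoding, character
    representations on or off, uni- versus bidirectional encoding,
    embedding fine-tuning), and the math core is verified against
    brute-force oracles. Includes CoNLL-style corpus readers and writers,
    IOB2 to BIEOS tag-scheme conversion, span-based micro-averaged
    precision/recall/F1 with alternative-annotation credit, word2vec text
    embedding loading, seeded synthetic corpus and embedding generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
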