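Package: accessnet
Title: Multi-Task Convolutional Models of Cell-Type-Specific DNA Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns the sequence determinants of open chromatin directly from
    DNA. Harmonizes per-cell-type accessibility peak calls (e.g. DNase-seq)
    into a fixed-width site set with a binary site-by-cell activity matrix,
    and trains a multi-task convolutional neural network that maps one-hot
    coded 600-bp sequence to per-cell accessibility probabilities. The
    network (valid convolutions, batch normalization, ReLU, max pooling,
    fully connected layers, sigmoid outputs) is trained by minibatch RMSprop
    with validation-based early stopping, and supports seeding a new
    single-target model from a pretrained multi-task model. Trained models
    are interrogated by distilling first-layer filters into position weight
    matrices, scoring filter influence via activation nullification, probing
    with motif insertion, in silico saturation mutagenesis, and SNP
    accessibility difference (SAD) profiles for variant interpretation. A
    seeded planted-motif grammar simulator generates full synthetic peak
    compendia (genome FASTA, per-cell BED, activity table, VCF of causal and
    bystander variants) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
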