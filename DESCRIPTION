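Package: gncn
Title: Neural Generative Coding Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical directed generative models trained without
    backpropagation. Layers of state neurons predict the layer below; error
    neurons compute precision-weighted mismatches; latent states settle over
    an iterative correction process and synapses adapt with local
    Hebbian-style rules. Implements the four generative neural coding network
    (GNCN) variants (t1/Rao, t1-Sigma/Friston, t2-LSigma, PDH), lateral
    group-competition sparsity, a Gaussian-mixture prior over top-layer codes
    with ancestral sampling, masked pattern completion, and the associated
    evaluation metrics (binary cross-entropy, Monte-Carlo marginal
    log-likelihood, masked MSE, linear-probe classification error, layer
    sparsity), plus a synthetic ground-truth generator so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
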