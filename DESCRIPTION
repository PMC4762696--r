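Package: nefradius
Title: Radius Optimization for Neural Engineering Framework Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building minimal Neural Engineering Framework (NEF)
    models of distributed vector representation with leaky integrate-and-fire
    neurons, and for optimizing the representational radius of ensembles that
    encode subvectors of high-dimensional unit vectors (semantic pointers).
    Implements the square-root-beta distribution of subvector lengths, an
    analytic radius-dependent distortion model with bounded scalar
    minimization, exact holographic-reduced-representation algebra (circular
    convolution binding, involution, unbinding, unitary vectors), and
    rate-mode and spiking benchmark circuits for representation,
    circular-convolution binding, and dot-product comparison, including the
    heuristic neuron-count reduction that the optimized radius affords.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
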