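Package: dietmix
Title: Bayesian Multi-Proxy Diet Mixing Models with Rank-Order Priors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Bayesian stable-isotope mixing models for diet
    reconstruction from multiple isotopic proxies (delta13C, delta15N,
    Delta14C), with concentration-dependent mixing, trophic discrimination
    offsets, and prior information encoded as rank-order (inequality)
    constraints on diet proportions, such as prey-preference orderings
    derived from DNA metabarcoding. Posteriors are sampled by a
    Metropolis-within-Gibbs sampler on the probability simplex with
    split-chain convergence diagnostics. Includes a synthetic-scenario
    generator for parameter-recovery experiments and a bundled case study
    on a subterranean (calcrete aquifer) invertebrate food web with three
    predatory diving beetles, comparing two-proxy, triple-proxy, and
    prior-informed model designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
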