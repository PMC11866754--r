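Package: restdnn
Title: Transferable Orbital-Pair Correlation Energy Learning with Low-Rank
    Fine-Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts electron correlation energies of molecules through a
    pairwise decomposition over localized occupied orbitals. Orbital-specific
    virtual (OSV) subspaces compress each orbital pair's excitation space into
    a small four-channel pseudo-energy descriptor tensor; a feed-forward
    neural functional maps descriptors to exact MP2 pair correlation energies,
    and a family of parameter-efficient fine-tuning methods (residual pair
    correction heads, low-rank weight adaptation, bias-only retraining, and a
    delta-learning baseline) adapts a pretrained base model to new regimes
    with very little data. Includes a compact restricted Hartree-Fock and
    canonical MP2 backend, Pipek-Mezey localization, deterministic synthetic
    fixture generators, and network diagnostics such as per-layer Frobenius
    update ratios and pair-error densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
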