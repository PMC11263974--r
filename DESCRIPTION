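Package: conformscape
Title: Pose-Conformation Disentanglement Benchmarks for Heterogeneous Cryo-EM Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic single-particle benchmark for studying whether
    latent-variable models of cryo-EM conformational heterogeneity separate
    particle pose from molecular conformation. Provides an analytic toy-particle
    simulator (articulated two-arm molecule, in-plane pose, Gaussian pixel
    noise) with i.i.d., temporal (Laplace-increment) and temperature-conditioned
    sampling regimes; variational autoencoders with an architecturally split
    pose/conformation latent space and a physics-based rotation decoder,
    trainable as a plain VAE, a PoseVAE (pose-intervention penalty) or a
    SlowVAE (temporal Laplace transition prior); a disentanglement metric suite
    (mean correlation coefficient, MIG, SAP, DCI disentanglement, modularity,
    BetaVAE and FactorVAE scores, pose-consistency score, rotation-invariance
    probe); MRCS/STAR/CSV particle-stack I/O; and a paired multi-seed benchmark
    runner with machine-readable comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
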