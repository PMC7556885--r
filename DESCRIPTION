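Package: hydrosub
Title: Anomalous Sub-Diffusion Analysis of Biomolecular Hydration Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for anomalous sub-diffusion of hydration
    water around biomolecules. Converts quasi-elastic neutron scattering
    dynamic structure factors S(q,nu) to susceptibility spectra via the
    Bose occupation factor, fits the Cole-Cole relaxation function per
    wave vector to extract relaxation times and the heterogeneity
    parameter alpha, turns the power-law scaling tau ~ q^-n into the
    sub-diffusion exponent beta = 2/n, extracts residence times from
    particle trajectories by sequential first passage to a displacement
    threshold (with hydration-layer resolution above a planar surface),
    and links mobility heterogeneity to sub-diffusion through a
    coarse-grained one-dimensional random-jump (continuous-time random
    walk) simulator driven by parametric or empirical waiting-time
    distributions. A synthetic-data module generates Cole-Cole spectra
    and heterogeneous-mobility trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
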