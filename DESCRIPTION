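Package: regenDXA
Title: Non-Invasive DXA Assessment of Regenerate Bone Versus Compression Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for relating dual-energy X-ray absorptiometry (DXA)
    measurements of regenerate bone formed during distraction osteogenesis
    to mechanical parameters obtained from compression testing to failure.
    Derives volumetric bone mineral density from dual-projection scans via
    an elliptical-cylinder model, extracts modulus, 0.2 percent offset
    yield, ultimate failure and strain-energy densities from
    load-displacement records, and compares density and mechanical
    parameters with Spearman rank correlation, simple linear regression,
    Fisher-z confidence intervals and post-hoc power. A Gaussian-copula
    synthetic-cohort generator with a tunable latent rank correlation
    between volumetric density and material parameters makes the whole
    pipeline testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
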