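Package: radassay
Title: Radiobiology Assay Analysis: DNA-Content Deconvolution, Clonogenic
    Survival and MTT Viability
Version: 1.0.0
Authors@R:
    person("Radassay", "Developers", email = "radassay@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for classical cellular radiobiology assays on
    cultured cells. Deconvolves propidium-iodide DNA-content histograms into
    five Gaussian subpopulations (sub-G1, G1, S, G2, polyploid) by bounded
    nonlinear least squares, with pulse width-vs-area doublet gating and
    G2-arrest kinetics across a post-irradiation time course. Fits the
    single-hit multi-target model S(D) = 1 - (1 - exp(-D/D0))^n to clonogenic
    survival data, reporting D0, the extrapolation number n and the
    quasi-threshold dose Dq. Computes MTT viability from 96-well optical
    density plates with blank and untreated normalisation and
    limit-of-quantification flagging. A seeded synthetic-data module
    generates flow-cytometry events, colony-count tables, OD plates and
    arrest time courses with the statistical structure each stage assumes,
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
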