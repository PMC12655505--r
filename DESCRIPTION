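Package: dermalpbk
Title: Bottom-Up Dermal Physiologically Based Kinetic Modelling for
    Topically Applied Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of finite-dose skin absorption in Franz
    diffusion cells (evaporating vehicle over stratum corneum, viable
    epidermis and dermis with partition-coupled diffusion), closed-form and
    fitted estimation of dermal parameters (Fick's-second-law membrane fits,
    evaporation kinetics, hepatic and renal clearance scaling), a whole-body
    perfusion-limited PBK model with single and repeated dermal dosing,
    two-stage refinement of chemical- and formulation-specific parameters
    against skin-penetration kinetics, and WHO-style model-performance
    machinery: non-compartmental PK metrics, 2-fold external validation,
    normalized local sensitivity with reliability classification,
    Monte-Carlo uncertainty, and population simulation. Includes synthetic
    data generators with known ground truth for every dataset shape the
    pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
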