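Package: hipoa
Title: Quantitative [18F]-NaF PET/MR Analysis of the Hip with a Synthetic Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated quantification workflow for hybrid [18F]-sodium-fluoride
    PET/MR imaging of hip osteoarthritis, validated end to end on a digital hip
    phantom with known ground truth. Provides standardized-uptake-value (SUV)
    mapping, image-derived arterial input function extraction, Patlak graphical
    analysis of the bone influx constant Kpat, voxelwise mono-exponential T1rho
    and T2 relaxometry of articular cartilage, PET-to-MR resampling and nonrigid
    registration with label propagation, principal-component statistical shape
    modeling of the proximal femur, semi-quantitative cartilage and bone-marrow
    lesion scoring with inter-rater agreement, and a correlation and partial-
    correlation association layer. The phantom module simulates dynamic PET with
    known kinetic parameters, relaxation-weighted MR stacks with known T1rho/T2,
    corresponded femur surfaces from a known low-rank shape space, and planted
    score-outcome correlations, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    e1071,
    vegan
Config/testthat/edition: 3
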