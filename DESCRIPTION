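Package: qpactsim
Title: Virtual Imaging Studies for Quantitative Photoacoustic Tomography of the Breast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual imaging testbed for three-dimensional
    quantitative photoacoustic computed tomography (qPACT) of the breast.
    Provides a stochastic numerical breast phantom generator with voxelwise
    optical and acoustic property maps, voxel Monte Carlo photon transport for
    optical fluence, a k-space pseudospectral acoustic solver with
    time-reversal reconstruction under mismatched medium assumptions,
    linear and fluence-compensated spectral unmixing baselines for blood
    oxygen saturation, a dual-task residual encoder-decoder (sO2 regression
    plus vessel/tumor segmentation) trained at toy scale, and the evaluation
    protocol (Frangi-based vessel/tumor separation, Dice, tumor detection
    counts, depth-binned sO2 error).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
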