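Package: scwave
Title: Quantification and Simulation of Surface Contraction Waves in Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify traveling cortical contraction waves from
    time-lapse images of large spherical cells such as starfish oocytes, and to
    simulate the mechanics and biochemistry that generate them. Includes a
    synthetic movie generator with ground truth, Chan-Vese level-set
    segmentation of the cell outline, curvature-radius kymographs and a
    wave-strength variance statistic, wavefront and isoline tracking, a
    triangulated-membrane mechanical model (bending, banded surface tension,
    in-plane elasticity, osmotic volume), an axisymmetric reaction-diffusion
    model of the cdk1-cyclinB/APC gradient, and Young-Laplace cortical tension
    from micropipette aspiration.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    Matrix,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
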