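Package: annulusEKF
Title: Automatic Aortic Annulus Measurement in 3D Echocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic measurement of the aortic annulus diameter in
    3D transoesophageal echocardiographic volume sequences. The left
    ventricular outflow tract and aortic root are modelled as a cylindrical
    Doo-Sabin subdivision surface whose pose and radial deformation states
    are estimated with an extended Kalman filter driven by edge detections
    along surface normals. Segmentation proceeds in two phases (stiff, then
    deformable) with bidirectional tracking over the cardiac cycle, and the
    annulus is quantified by a least-squares ellipse fit to the intersection
    of the surface with the annulus disc plane. Includes a synthetic
    speckle-noise phantom generator with exact ground truth for validation
    and sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
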