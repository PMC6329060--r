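Package: pelvinc
Title: Pelvic Incidence Measurement from CT-Derived 3D Pelvic Models
Version: 0.1.0
Authors@R:
    person("pelvinc", "developers", email = "pelvinc@example.org",
           role = c("aut", "cre"))
Description: Measures the pelvic incidence (PI) angle from CT volumes or
    pre-extracted pelvic surface meshes. The pipeline covers Hounsfield-unit
    thresholding with seeded region growing, marching-tetrahedra isosurface
    reconstruction with Taubin smoothing, anterior-pelvic-plane alignment from
    ASIS and pubic-tubercle landmarks, least-squares sphere fitting of both
    acetabula to locate the hip axis, mid-sagittal symmetry-plane estimation
    by iterative closest points, orthogonal line fitting of projected sacral
    endplate points, and the PI angle itself, together with an endplate
    concavity classifier (type 1 / type 2 / flat). A parametric pelvis
    phantom with analytically known PI makes every stage testable without
    external data, and intraclass-correlation reliability statistics
    (ICC(2,1), ICC(3,1)) plus cohort comparison utilities mirror the usual
    validation workflow. Includes minimal DICOM/NIfTI/NRRD/PLY/STL I/O and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
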