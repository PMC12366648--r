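Package: spaceform
Title: Closed-Form Principal Component Analysis in Spherical and Hyperbolic Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Space form PCA (SFPCA): closed-form estimation of Riemannian affine
    subspaces for data on constant-curvature manifolds. Spherical PCA reduces to an
    ordinary eigendecomposition of the second-moment matrix; hyperbolic PCA solves an
    indefinite (Lorentzian J-)eigenequation on the hyperboloid model. Includes
    geodesic projection with closed-form distances, isometries onto low-dimensional
    space forms, a principal geodesic analysis (PGA) baseline, a synthetic benchmark
    with normalized output errors, a compositional-data pipeline on the sphere
    (Aitchison, Jensen-Shannon, total-variation and geodesic distortion metrics),
    and a gene-tree pipeline (patristic distances, hyperbolic embedding, quartet
    scores, and eigen-spectrum knee-point outlier ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
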