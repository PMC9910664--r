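Package: patsr
Title: Pulmonary Air and Tissue Segmentation for Mouse Thoracic MicroCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated segmentation and 3D morphometry of mouse thoracic
    micro-computed tomography volumes. Implements a scriptable task-list
    engine for pulmonary air and tissue segmentation (PATS): global
    thresholding, per-slice ROI shrink-wrap, connected-component
    despeckling, round/square binary morphology, and the canonical in vivo
    and ex vivo task lists. Morphometry covers aerated and tissue volumes,
    volume-weighted local structure thickness, directed-secant structure
    linear density, and closed triangle-mesh surface models exported as
    STL. A synthetic thorax phantom generator with voxel-level ground
    truth (body, lung air, vessels, lesions, heart) supports end-to-end
    validation without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
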