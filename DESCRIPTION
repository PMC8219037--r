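Package: scleromorph
Title: 3D Morphometry of Lobed Sclereids and Raman Hyperspectral Unmixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional shape transformation of
    polylobate sclereids (3D puzzle cells, e.g. in walnut shell tissue)
    from labeled segmentation volumes: cell volume and surface area,
    convex-hull solidity, largest empty sphere, skeleton-based lobe
    counting, cell-cell contact areas with patch fragmentation, and
    wall-thickness loop mapping.  Includes a Raman hyperspectral
    workflow (cosmic-ray despiking, band integration, non-negative
    matrix factorization endmember extraction, non-negative orthogonal
    matching pursuit against a reference library, marker-band peak
    localization), stage-comparison statistics (Kruskal-Wallis with
    Dunn's post hoc), and a synthetic phantom generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
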