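Package: tractatlas
Title: Data-Driven Fiber-Cluster Atlases for Whole-Brain Tractography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated identification of white-matter fiber tracts from
    whole-brain tractography. Provides readers and writers for streamline
    files (VTK legacy and XML polydata, TrackVis), binary NIfTI masks and
    JSON transforms; pairwise fiber distances with Gaussian-kernel
    affinities and a bilateral (midsagittal-mirror) option; unbiased
    entropy-based groupwise registration of tractography with affine and
    cubic b-spline stages; Nystrom spectral embedding and k-means
    clustering of fibers with leave-one-out fiber probabilities and
    iterative outlier rejection to build a fiber-cluster atlas; atlas
    application to new subjects including registration, out-of-sample
    embedding, nearest-cluster assignment, outlier removal and hemisphere
    splitting; anatomical-hierarchy tract extraction; and quantitative
    evaluation via signed distances from tracts to activation masks,
    cluster-consistency summaries and tract volumes. Seeded synthetic-data
    generators (bundles, bilateral cohorts, planted outliers, simulated
    tumors, spherical activation masks) support fully reproducible testing
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
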