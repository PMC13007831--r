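Package: thalnet
Title: Seizure-Onset-Zone to Thalamus Connectivity and Stimulation Engagement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific structural connectivity analysis for thalamic
    responsive neurostimulation in drug-refractory epilepsy. Provides
    probabilistic streamline tractography from seizure-onset-zone (SOZ)
    regions to a thalamic segmentation over synthetic fiber-orientation
    phantoms, track-visitation probability maps with 95% mass thresholding,
    an analytic point-source model of the stimulation electric field
    thresholded into a volume of tissue activated (VTA), the two
    engagement metrics (proportion of SOZ streamlines inside the VTA and
    peak connection probability within the VTA), a convergent/transthalamic
    connectivity-pattern classifier, and the nonparametric outcome
    statistics (exact Mann-Whitney U, Spearman rank correlation) relating
    engagement to seizure reduction. Includes a synthetic-cohort generator
    with geometric ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
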