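Package: dyadsync
Title: Dyadic Inter-Subject Trajectory Similarity of Multi-Voxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking dyadic similarity of multi-voxel
    neural-pattern trajectories to marital satisfaction. Builds TR-by-TR
    pattern-trajectory matrices per subject and region of interest, computes
    inter-subject trajectory similarity (ISTS) for married couples and
    derangement-based random pairings with class-wise z normalisation,
    segments network activity into ordered neural events with a no-return
    hidden Markov model selected by nested cross-validation, computes
    within-event and within-movie-clip ISTS, and relates regional ISTS to
    satisfaction scores with PLS-1 regression, permutation testing,
    bootstrap z values and false-discovery-rate control. Includes a
    synthetic dyadic BOLD generator with known coupling and event structure
    so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
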