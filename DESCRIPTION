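Package: tedfmri
Title: Task-Related Edge Density Analysis for Task fMRI
Version: 0.1.0
Authors@R:
    person("TED", "Developers", email = "ted-dev@example.org",
           role = c("aut", "cre"))
Description: Detects task-related formation of voxel-level brain networks in
    block-design fMRI experiments. For every voxel pair the package computes a
    differential synchronisation score between two task conditions from
    trial-locked effect-size time courses, normalises the scores by a
    rank-preserving Gaussian transform, scores suprathreshold edges by the
    local edge density between the 26/18/6-neighbourhoods of their endpoints,
    and assesses significance with an empirical false-discovery rate derived
    from task-label permutations. Includes NIfTI-1 input/output, a
    synthetic-data generator with planted synchronised clusters and
    controllable inter-trial consistency, hubness maps, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
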