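Package: actionchunks
Title: Operant Schedule Simulation, Action-Sequence Chunking Analysis and
    Regional Activation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing single-lever operant
    conditioning sessions at 10-ms timestamp resolution. Implements the
    reinforcement schedules used in sequence-training studies (continuous
    reinforcement, random ratio, a sequence-trigger gate, lever-hold and
    random-time schedules), a synthetic-agent generator with ground-truth
    annotations, parsing of event streams into action sequences with
    initiation/execution/termination elements, inter-press-interval and
    sequence-boundary chunking analyses, recovery of true inter-press
    intervals from session audio, and neuronal activation mapping on
    section images (soma detection, polygonal atlas assignment, regional
    counts and cross-correlation analyses).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    signal,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
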