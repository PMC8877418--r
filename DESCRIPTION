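Package: ehtforce
Title: Contractile Force Analysis for Cantilever-Based Engineered Heart Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Video-based contractility analysis for engineered heart tissues (EHTs)
    suspended between marker-tipped PDMS cantilevers. Tracks the two carbon-black
    cantilever tops in brightfield image stacks, converts the inter-marker
    deflection to contraction force through the elastic beam bending equation,
    segments paced twitches and extracts kinetic readouts (peak force,
    contraction/relaxation velocities, times to 10%/90% of each phase), fits
    descending Hill concentration-response curves for negative inotropy (IC50),
    and computes tissue compaction, success-rate and seeding-dose bookkeeping.
    Includes a synthetic-fixture generator (rendered marker videos, parametric
    twitch traces, dose tables, tissue silhouettes) with analytic ground truth,
    and a command-line front-end for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
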