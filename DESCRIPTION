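Package: fluxvar
Title: Parallel Flux Variability Analysis with Dynamic Load Balancing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux variability analysis (FVA) of constraint-based metabolic
    models as a sweep of 2n linear programs, distributed over a two-level
    worker hierarchy with static, guided, or dynamic (chunked work-queue)
    load balancing and per-worker telemetry. Includes a solver-agnostic LP
    layer with a bounded-variable revised simplex backend supporting basis
    warm starts between successive subproblems, generation of warmup points
    for flux-space sampling (FVA witnesses plus optima of random objectives),
    free-format MPS reading and writing, a converter for COBRA-style
    structured model containers, a synthetic model generator for
    desk-scale verification, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
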