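Package: cellcontacts
Title: Quantifying Cell-Cell Interactions During Electrotaxis from Labeled Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cell-cell interactions in time-lapse
    microscopy of migrating cells, with or without an applied direct-current
    electric field (electrotaxis). From per-frame integer label masks the
    package detects cell-cell contacts by pixel adjacency, builds contact
    events and clusters, fits moment-equivalent ellipses to cell shapes,
    localizes each contact on the cell surface relative to the moving front,
    and computes two per-contact response metrics: contact inhibition of
    locomotion (CIL, the cosine between the velocity-change direction and the
    away-from-neighbour direction) and velocity alignment (the change in
    cosine similarity of the two cells' velocities across the contact).
    Responses are aggregated into contact-position by neighbour-speed maps
    with a four-way behaviour classification. An agent-based simulator of
    persistent random walkers with tunable electrotactic bias and collision
    responses generates labeled movies with ground truth, so the full
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
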