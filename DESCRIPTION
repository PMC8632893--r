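Package: toolscape
Title: Agent-Based Simulation of Primate Stone-Tool Transport and the
    Material Record It Leaves Behind
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit agent-based model of primate nut-cracking
    tool transport on a bounded grid. Primates random-walk through a forest of
    nut trees, acquire stone pounding tools from raw-material sources or re-use
    previously discarded tools, carry them short distances to trees, and
    discard them after use; tools stochastically break, shedding fragments,
    and are exhausted below a mass threshold; trees age, die, and regrow
    nearby. Repeated short transport bouts redistribute stone across the
    landscape over tens of thousands of time-steps. The package provides a
    compiled simulation core, seeded factorial parameter sweeps, and a tidy
    analysis layer computing tool-use-location growth, maximum tool
    displacement, per-cell assemblage composition, and distance-decay
    structure of the resulting material record.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
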