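Package: cidyn
Title: Cultural-Identity Dynamics Under Terrorist Threat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based model of cultural-identity dynamics under a terrorist
    threat. Agents hold acceptance segments (latitudes of acceptance) over K
    cultural worldviews, form attitudes about each other from segment
    similarity, and contract their margins of acceptance when an extremist
    identity threatens them. Virtual populations are synthesized by particle
    swarm optimization so that their group-to-group attitude statistics match
    survey-derived targets, then exposed to a threat scenario whose per-agent
    attitude evolutions are classified as increasing or
    decreasing-or-unchanged. Includes a synthetic survey generator emulating
    the record structure of the calibration survey, population/scenario IO,
    and a reproducible experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
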