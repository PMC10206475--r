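Package: matrinet
Title: Ontogeny of Social Networks in Matrilineal Primate Troops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how immature animals inherit and then
    differentiate from their mothers' social networks, built around the
    field protocols used for wild chacma baboons. Constructs time-aggregated
    proximity (simple-ratio-index) and directed grooming networks from scan
    and ad libitum observation records, computes I&SI dominance ranks,
    node-level network metrics, ego-network similarity and partner-composition
    responses, fits the corresponding (generalized) linear mixed models, and
    assesses effects against datastream (checkerboard-swap) and node-label
    permutation null models. A synthetic troop generator with known ground
    truth supports parameter-recovery and null-calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
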