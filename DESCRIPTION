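Package: bteval
Title: Evaluation Toolkit for Bacteria-Track Information Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reads and writes BioNLP-style standoff annotations (including
    discontinuous entity spans, nested events, ontology normalizations and
    equivalence sets), infers gene regulation networks from text-bound event
    annotations through a two-step rule engine, and scores predictions
    against references. Network predictions are scored with the Slot Error
    Rate (substitutions, deletions, insertions over reference arcs) in
    official, shape and effect modes; bacteria-biotope entity and event
    predictions are scored with a graded similarity combining a segment
    Jaccard index over possibly discontinuous spans with Wang semantic
    similarity over an OBO ontology, using optimal one-to-one pairing.
    Includes deterministic generators for synthetic ontologies, annotated
    documents, networks and error-injected predictions with known
    ground-truth error counts.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
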