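# bteval

Evaluation toolkit for bacteria-track biomedical information extraction:
gene regulation network (GRN) inference from text-bound event annotations,
and graded scoring of regulation-network and bacteria-biotope (BB)
predictions.

## The problem

Information extraction systems for microbiology produce two kinds of
structured predictions from text:

1. **Gene regulation networks** — directed labeled graphs whose nodes are
   genes and whose arcs carry one of six interaction types (effect types
   *Activation*, *Inhibition*, *Requirement*, *Regulation*; mechanism types
   *Binding*, *Transcription*). Systems may submit either the network
   itself or text-bound events, from which the network is inferred by rules
   in two steps: molecular events (protein binding to a site, a promoter
   driving a gene, regulon membership) are first saturated into biological
   `Interaction:*` events, whose arguments — possibly nested events — are
   then reduced to their participating genes to yield arcs.
2. **Bacteria biotopes** — text-bound `Bacteria`, `Habitat` and
   `Geographical` entities (spans may be discontinuous), habitat
   categorization against a hierarchical ontology, and binary
   `Localization` / `PartOf` events between entities.

Evaluating such predictions fairly requires partial credit: an arc with the
wrong label, a habitat with slightly wrong boundaries, or an ancestor
category instead of the exact one are better than nothing. The package
implements the corresponding scorers:

* **Slot Error Rate** for networks:
  `SER = (S + D + I) / N`, with substitutions `S` (right arc, wrong
  label), deletions `D`, insertions `I` over `N` reference arcs, reported
  alongside recall `M/N`, precision `M/P` and F1 — in *official*, *shape*
  (topology only) and *effect* (effect labels only) modes, with inversion
  errors (swapped agent/target) reported separately.
* **Graded entity similarity** for BB sub-task 1:
  `S = Sc · Se`, where `Se` is a segment Jaccard index over (possibly
  discontinuous) character spans and `Sc` the Wang semantic similarity
  between assigned and reference ontology concepts;
  `SER = (Σ(1−S) + D + I) / N`, `recall = ΣS/N`, `precision = ΣS/P`.
  Reference and predicted entities are paired one-to-one over overlapping
  pairs so as to maximize the total similarity (optimal bipartite
  matching).
* **Event F1** for BB sub-tasks 2/3: strict matching for the bacterium
  argument (any member of an equivalence set of mentions is valid), `Se`
  grading for biotope arguments, with relaxed-boundary and intra-sentence
  analysis modes.

A fixtures module generates synthetic ontologies, annotated documents and
networks, and injects controlled error counts so every scorer can be
validated against known ground truth.

## Worked example

```r
library(bteval)

# a 12-arc reference network and a prediction with known injected errors
ref <- generate_network(n_genes = 10, n_arcs = 12, seed = 42)
perturbed <- perturb_network(ref, error_spec(n_delete = 2, n_insert = 3,
                                             n_substitute = 1, seed = 7))
evaluate_network(ref, perturbed$prediction)
#> <network_score [official]: SER=0.5000 recall=0.7500 precision=0.6923 F1=0.7200>
#> <arc_diff: N=12 P=13 | M=9 S=1 D=2 I=3 (inversions: 0, policy del-ins)>
evaluate_network(ref, perturbed$prediction, mode = "shape")
#> <network_score [shape]: SER=0.4167 recall=0.8333 precision=0.7692 F1=0.8000>
#> <arc_diff: N=12 P=13 | M=10 S=0 D=2 I=3 (inversions: 0, policy del-ins)>
```

The official diff recovers exactly the injected errors — 1 substitution, 2
deletions, 3 insertions over 12 reference arcs, so `SER = 6/12 = 0.5`. In
shape mode labels are dropped, the substitution disappears (`S = 0`) and
the SER improves to `5/12`.

```r
onto <- generate_ontology(depth = 4, branching = 3, seed = 1)
doc  <- generate_bb_document(bb_profile(), onto, seed = 1)
pred <- perturb_entities(doc, error_spec(n_delete = 1, n_insert = 1,
                                         seed = 2), onto)
score_subtask1(doc, pred$prediction, onto)
#> <bb_entity_score>
#>   official       SER=0.3333 recall=0.8333 precision=0.8333 F1=0.8333 (N=6 P=6 D=1 I=1)
#>   detection      SER=0.3333 recall=0.8333 precision=0.8333 F1=0.8333 (N=6 P=6 D=1 I=1)
#>   categorization SER=0.3333 recall=0.8333 precision=0.8333 F1=0.8333 (N=6 P=6 D=1 I=1)
score_events(doc, doc, subtask = 2, intra_sentence = TRUE)
#> <bb_event_score sub-task 2, intra-sentence>
#>   overall       recall=1.0000 precision=1.0000 F1=1.0000 (N=3 P=3)
#>   Localization  recall=1.0000 precision=1.0000 F1=1.0000 (N=2 P=2)
#>   PartOf        recall=1.0000 precision=1.0000 F1=1.0000 (N=1 P=1)
```

One deleted and one inserted habitat over six references give
`SER = 2/6`; the self-comparison of events is perfect, and intra-sentence
mode keeps only the events whose arguments share a sentence.

## Command line

```sh
inst/cli/bteval gen-ontology --depth 4 --branching 3 --seed 1 --out onto.obo
inst/cli/bteval gen-bb --onto onto.obo --docs 2 --seed 5 --out-dir corpus/
inst/cli/bteval bb-score --subtask 1 --ref corpus/ --pred corpus/ --onto onto.obo
inst/cli/bteval gen-grn --genes 8 --arcs 10 --seed 3 --out ref.net
inst/cli/bteval perturb --ref ref.net --delete 2 --insert 1 --seed 4 --out pred.net
inst/cli/bteval grn-score --ref ref.net --pred pred.net --mode official --report json
```

`grn-score` also accepts standoff corpus directories (inference is applied
first) and GraphML files.

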