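---
title: "Scoring models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bteval)
```

This vignette explains what the package computes and why it is built the
way it is: the annotation model, the network inference rules, the three
scoring families (Slot Error Rate over networks, graded entity similarity,
event F1), the knobs that matter, what the synthetic-data generators do and
do not emulate, and the design decisions taken where more than one faithful
reading existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Standoff annotations

Documents are plain text; annotations reference the text by 0-based,
half-open character offsets in Unicode code points (the convention of the
BioNLP shared-task standoff format, which the dialect here follows). An
entity covers one or more disjoint fragments: discontinuous spans arise
from shared heads in coordinations ("animal and human intestine" contains
the discontinuous entity *animal intestine*) and from range constructions.
The joined surface string uses a single space between fragments and is
informational only — every scorer works on offsets, never on surfaces.

Events map role names to arguments. In the gene-regulation schema
arguments may themselves be events (nesting); in the bacteria-biotope
schema they are entities only. Equivalence sets (groups of interchangeable
entity mentions) are symmetric and transitively closed at parse time, so
membership lookup is a single scan. Unknown annotation kinds are preserved
verbatim with a warning rather than rejected, because predictions from
heterogeneous systems vary in what extra lines they emit.

Multi-concept normalizations are accepted both as repeated lines sharing
one id and as comma-separated concept lists; serialization always emits one
line per concept, which round-trips under the parser's accumulation rule.

## Network inference

The annotation model has two levels. Molecular events record low-level
phenomena: a protein binding a site (`Bind_to`), a site belonging to a
promoter (`Site_of`), a promoter driving a gene (`Promoter_of`),
transcription by a protein from a promoter (`Transcription_by` /
`Transcription_from`), and regulon membership (`Master_of_Regulon` /
`Member_of_Regulon`). Inference proceeds in two steps:

1. **Molecular to biological.** A declarative rule registry
   (`grn_rules()`) is saturated to a fixpoint: binding a site of a
   promoter yields `Master_of_Promoter`; that plus `Promoter_of` yields
   `Interaction:Binding`; transcription from a promoter of a gene by a
   protein yields `Interaction:Transcription`; mastering a regulon that a
   gene belongs to yields `Interaction:Regulation`. Each derived event is
   added once per (type, arguments) signature, so the step is idempotent.
   Rules whose semantics the annotation model does not pin down (e.g.
   `Transcription_by` with no promoter in sight) exist in the registry but
   are flagged `provisional` and excluded by default — they are never
   guessed silently, and a replacement registry can be passed in.
2. **Biological to arcs.** Every `Interaction:L` event contributes arcs
   `(a, t, L)` for each agent gene and target gene of its arguments.
   Arguments are reduced to genes recursively: a protein stands for the
   gene encoding it (they share one node — the entity's normalization
   string, falling back to its surface, is the node name, matched
   case-sensitively and exactly); promoters and sites follow their
   `Promoter_of`/`Site_of` attachment; events take the union over their
   arguments. Recursion depth is capped at 10 as an anti-cycle guard.
   Repeated interactions collapse to one arc; self-loops are kept with a
   warning, since autoregulation is real biology.

A network submitted directly as an arc list is equivalent to inference
over a document carrying the corresponding flat interaction events; the
test suite asserts this round trip.

## Slot Error Rate over networks

Arc errors are counted per ordered gene pair and summed. On a pair, equal
labels match; leftover reference and predicted labels pair up as
substitutions; the remainder are deletions (reference side) and insertions
(prediction side). Then

$$\mathrm{SER} = \frac{S + D + I}{N},$$

which is 0 for a perfect prediction and unbounded above. Recall $M/N$,
precision $M/P$ and F1 are reported for convenience, but they count a
substitution twice — once against recall and once against precision —
while the SER counts it once; the suite demonstrates the arithmetic by
comparing a pure-substitution prediction with a pure-deletion one of equal
SER and strictly higher F1.

**Inversions.** A prediction that swaps agent and target is reported
separately. Two counting policies are implemented because the source
material does not settle the question: the default `del-ins` policy counts
the inverted arc as a deletion plus an insertion (the plain graph-diff
reading); `substitution` folds each inversion into a single substitution.
`M + S + D = N` holds under both.

**Shape mode** removes labels from both networks and collapses parallel
arcs, so no substitution can remain. Direction is kept by default — the
reading most consistent with label removal being the *only* change — with
an `undirected` switch for the coarser reading. A caveat discovered while
testing: the claim that shape-mode F1 ranking always equals SER ranking is
not a theorem, because F1 weighs deletions more than insertions (with
$N=12$: $D{=}4, I{=}0$ gives SER $0.33$, F1 $0.80$; $D{=}0, I{=}5$ gives
SER $0.42$ but F1 $0.83$). The property does hold on families ordered by
total error count, which is what the invariant test checks.

**Effect mode** removes the mechanism types: a mechanism arc between two
genes becomes a generic `Regulation` arc, unless effect arcs already
connect the pair, in which case it is dropped as redundant. When both
`Binding` and `Transcription` would map to `Regulation` on one pair, the
duplicates collapse to a single arc.

F1 is defined as 0 whenever `P = 0` or `M = 0` (never `NaN`); an empty
reference network is an error, since SER is undefined at `N = 0`.

## Graded entity scoring

Sub-task-1 scoring combines two similarities per (reference, prediction)
pair:

* **Boundary similarity** `Se`: the Jaccard index over the sets of
  character offsets covered by all fragments of each entity. This extends
  the segment-overlap ratio naturally to discontinuous spans, and gives
  the fixed points asserted in the acceptance suite
  (`[0,10)` vs `[5,15)` → 1/3; `{[0,6),[17,26)}` vs `[0,6)` → 0.4).
* **Category similarity** `Sc`: Wang similarity between assigned ontology
  concepts. For each concept, S-values decay by a per-relation factor `w`
  per edge toward the root ($S_X(X)=1$;
  $S_X(t)=\max_{c} w \cdot S_X(c)$ over children $c$ of $t$ inside $X$'s
  ancestor closure), and
  $$\mathrm{sim}(a,b) = \frac{\sum_{t \in T_a \cap T_b} S_a(t) + S_b(t)}
  {SV(a) + SV(b)}.$$
  The measure is symmetric, exactly 1 on identical concepts, favors
  ancestor over sibling predictions, and decays strictly along `is_a`
  chains — the properties that make partial credit for over-general
  categories meaningful. The default factor is `w = 0.8` for `is_a`, the
  canonical value of the method; it is configurable per relation
  (`wang_config()`) because the factor used by the original evaluation
  service is not published, and other relations (`part_of`, ...) fall
  back to a configurable default and otherwise participate identically.
  S-values are propagated in topological order over the ancestor closure,
  which terminates on any DAG and needs no memo invalidation.

  Multi-label aggregation is a design decision: the default is the mean
  over reference concepts of the best similarity to any predicted concept,
  with an optimal one-to-one `max_matching` alternative. An empty
  reference concept set means categorization is not required (`Sc = 1`);
  an empty prediction against a non-empty reference scores 0.

The combined similarity is `S = Sc · Se`. Entities are paired one-to-one,
only across pairs that share at least one character (any overlap — the
threshold that makes "insertion" and "deletion" coincide with
"overlaps nothing"), choosing the matching that maximizes the summed
similarity, i.e. the participant's score. The matching is computed as a
maximum-weight bipartite matching (igraph backend); the test suite
validates its optimality against exhaustive enumeration on all instances
with up to 6 entities per side. A tiny epsilon (`1e-9`) is added to every
eligible edge so that, at equal total similarity, pairings covering more
overlapping pairs win — an overlapping pair of similarity 0 then counts as
one substitution (cost 1) rather than a deletion plus an insertion
(cost 2), matching the overlap-based definitions of those error types.

Scores follow: `D` unmatched references, `I` unmatched predictions, a
substitution mass of `1 − S` per pair, `SER = (Σ(1−S) + D + I)/N`,
`recall = ΣS/N`, `precision = ΣS/P`. Three variants are always computed:
`official` (`S = Sc·Se`), `detection` (`S = Se`, categorization ignored)
and `categorization` (`Se` forced to 1 on paired entities). Each variant
re-runs the pairing with its own similarity, since the optimal matching
depends on what is being maximized.

## Event scoring

Candidate event pairs must have equal type. The bacterium argument of a
`Localization` event is matched strictly — the predicted span must equal
the reference argument's span or the span of **any** member of its
equivalence set (a factor of 1 or 0). Biotope arguments are graded by
`Se`; for `PartOf` both arguments are habitats, so both are graded and
their contributions multiply (the strict-equality clause is read as
bacteria-specific). Events are then paired one-to-one maximizing the total
score — the same principle as entity pairing, extended to events as a
design decision — and `recall = Σscore/N`, `precision = Σscore/P`, with
per-type breakdowns.

Two analysis modes mirror published result tables: `relax_boundaries`
lifts any overlapping biotope argument to full credit (relaxed scores
dominate official ones on every fixture, by construction of the
relaxation), and `intra_sentence` keeps only events whose arguments fall
inside a single sentence span on both sides. Intra-sentence mode requires
sentence spans; by default their absence is a configuration error, and an
explicit `sentence_fallback = TRUE` opts into a crude period-plus-capital
splitter whose use is flagged in the report (the original analysis used
gold sentences, so the fallback is never silent).

Corpus-level aggregation is micro by default (counts and similarity masses
pooled before ratios), matching single-number task-level results; macro
averaging is available by flag since the original averaging mode is
unstated.

## Synthetic fixtures

The generators state a world and keep it fixed:

* `generate_ontology(depth, branching)` builds a rooted `is_a` tree
  (optionally DAG-ified by cross-links to strictly shallower levels, which
  preserves acyclicity); depth 10 and ~1,800 concepts — the published
  scale of the habitat ontology — are reachable but tests run at desk
  scale (depth 3–4).
* `generate_bb_document()` defaults mirror published corpus statistics
  where they exist: 1.8% discontinuous entities, 54% intra-sentence
  Localization arguments, 63% for PartOf, three quarters of events
  Localization. Where no value is stated the defaults are modest desk-
  scale choices fixed once: 12 entities and 6 events per document
  (the real corpus averages ~40 and ~18 — size does not change any scored
  ratio), equivalence sets over 10% of repeated bacterium names, 5%
  multi-concept normalizations, and a 25% chance of a geographical
  mention per sentence. A Monte-Carlo test over 200 documents checks the
  realized intra-sentence rate to ±0.05.
* `perturb_network()` / `perturb_entities()` inject **exactly** the
  requested error counts under placement constraints that make them
  identifiable downstream (substituted labels differ from every reference
  label on the pair; insertions land on pairs or text stretches free of
  reference items; inverted arcs land on reverse pairs free in the
  reference). The error-recovery acceptance criterion rests on these
  constraints.
* Every generator takes an explicit seed, uses a local RNG stream and
  restores the caller's RNG state; identical seeds give byte-identical
  output.

What the generator does **not** emulate: real linguistic variation
(fixture text is template filler), anaphora, entity repetition statistics,
the published corpora themselves, or participant-system error profiles. A
green test therefore establishes that the scorers implement their
definitions exactly and behave correctly under controlled error injection
— not that any particular published system score is reproduced, which
would require the non-public test data.

## Numerical choices

* All counts are integer; SER/recall/precision are computed as single
  divisions of exact sums, so self-comparisons give SER exactly 0 and the
  error-recovery tests can assert machine-precision equality.
* Wang similarity of a concept with itself is exactly 1 (numerator and
  denominator are the same doubled sum).
* Matching epsilon `1e-9` (see above) is far below any attainable
  similarity difference at fixture scale (similarities are small
  rationals), so it only ever breaks exact ties.
* `harmonic_f1` returns 0 when recall + precision is 0.
* Greedy one-to-one pairing of deleted/inserted arcs detects inversions;
  with at most one arc per (pair, label) the greedy pairing is exact.

## Known limitations

* The GRN schema's role names (`Agent`, `Target`, `Site`, ...) are this
  package's own; corpora using different role labels need a light rename
  on input.
* The complete official inference rule set is not published in the source
  material; the registry covers every rule named or illustrated there and
  accepts drop-in replacements, with provisional entries excluded by
  default.
* Sub-task 1 counts each reference entity once even when it belongs to an
  equivalence set (the official denominator convention is unstated).
* The event scorer assumes the two documents share the underlying text; it
  does not verify document identity beyond ids.
* No statistical comparison between submissions, no visualization beyond
  GraphML export, and no text-level prediction of any kind: input is
  always annotations.
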