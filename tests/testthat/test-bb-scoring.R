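test_that("one ref with two overlapping predictions keeps the better one", {
  ref <- list(entity("R1", "Habitat", "0 10"))
  preds <- list(entity("P1", "Habitat", "0 8"),   # Se = 0.8
                entity("P2", "Habitat", "5 15"))  # Se = 1/3
  p <- pair_entities(ref, preds)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$pred, 1L)
  expect_equal(p$pairs$similarity, 0.8)
  expect_equal(p$unmatched_pred, 2L)
})

test_that("crossed overlaps resolve to the maximum-total assignment", {
  refs <- list(entity("R1", "Habitat", "0 10"),
               entity("R2", "Habitat", "8 20"))
  preds <- list(entity("P1", "Habitat", "0 12"),
                entity("P2", "Habitat", "9 20"))
  p <- pair_entities(refs, preds)
  w <- outer(refs, preds, Vectorize(segment_similarity))
  expect_equal(sum(p$pairs$similarity), oracle_best_matching(w),
               tolerance = 1e-9)
  expect_equal(nrow(p$pairs), 2L)
})

test_that("non-overlapping entities are never paired", {
  refs <- list(entity("R1", "Habitat", "0 5"))
  preds <- list(entity("P1", "Habitat", "10 15"))
  p <- pair_entities(refs, preds)
  expect_equal(nrow(p$pairs), 0L)
  expect_equal(p$unmatched_ref, 1L)
  expect_equal(p$unmatched_pred, 1L)
})

test_that("pairing total equals the exhaustive maximum on random instances", {
  set.seed(99)
  for (k in 1:60) {
    refs <- random_entities(sample.int(5, 1), prefix = "R")
    preds <- random_entities(sample.int(5, 1), prefix = "P")
    p <- pair_entities(refs, preds)
    w <- outer(refs, preds, Vectorize(segment_similarity))
    eligible <- outer(refs, preds,
                      Vectorize(function(a, b)
                        bteval:::entities_overlap(a, b)))
    expect_equal(sum(p$pairs$similarity),
                 oracle_best_matching(w, eligible), tolerance = 1e-6)
  }
})

test_that("sub-task 1 self-comparison is perfect; partial overlap is graded", {
  onto <- generate_ontology(3, 2, seed = 4)
  doc <- generate_bb_document(bb_profile(), onto, seed = 21)
  s <- score_subtask1(doc, doc, onto)
  expect_equal(s$official$SER, 0)
  expect_equal(s$official$recall, 1)
  expect_equal(s$official$precision, 1)

  # one ref habitat, prediction with Se = 1/3 and a correct concept:
  # [0,14) vs [7,21) overlap on 7 of 21 offsets
  text <- "thermal spring waters"
  concept <- names(onto$concepts)[2]
  ref <- standoff_document("d", text,
    entities = list(entity("T1", "Habitat", "0 14")),
    normalizations = list(normalization("N1", "T1", concept)))
  pred <- standoff_document("d", text,
    entities = list(entity("T1", "Habitat", "7 21")),
    normalizations = list(normalization("N1", "T1", concept)))
  expect_equal(segment_similarity(ref$entities$T1, pred$entities$T1), 1 / 3)
  sc <- score_subtask1(ref, pred, onto)
  se <- 1 / 3
  expect_equal(sc$official$recall, se)
  expect_equal(sc$official$SER, 1 - se)
  expect_equal(sc$categorization$recall, 1) # Se forced to 1 on pairs
  expect_equal(sc$detection$recall, se)
  expect_error(score_subtask1(standoff_document("d", "x"), pred, onto),
               class = "bteval_undefined_reference")
})

test_that("injected deletions and insertions are recovered exactly", {
  onto <- generate_ontology(3, 3, seed = 8)
  for (seed in 1:8) {
    doc <- generate_bb_document(bb_profile(entities_per_doc = 15), onto,
                                seed = seed)
    N <- sum(vapply(doc$entities, function(e) e$type == "Habitat", TRUE))
    d <- min(2L, N - 1L)
    p <- perturb_entities(doc, error_spec(n_delete = d, n_insert = 2,
                                          seed = seed + 50), onto)
    sc <- score_subtask1(doc, p$prediction, onto)
    expect_equal(sc$official$D, d)
    expect_equal(sc$official$I, 2L)
    expect_equal(sc$official$SER, (d + 2) / N)
  }
})

test_that("boundary jitter produces substitutions only", {
  onto <- generate_ontology(3, 2, seed = 3)
  doc <- generate_bb_document(bb_profile(discontinuity_rate = 0), onto,
                              seed = 33)
  N <- sum(vapply(doc$entities, function(e) e$type == "Habitat", TRUE))
  p <- perturb_entities(doc, error_spec(n_substitute = 2,
                                        boundary_jitter = 2, seed = 60),
                        onto)
  sc <- score_subtask1(doc, p$prediction, onto)
  expect_equal(sc$official$D, 0L)
  expect_equal(sc$official$I, 0L)
  expect_equal(sc$official$matched, N)
  expect_gt(sc$official$substitution, 0)
  expect_equal(sum(sc$official$pairs$similarity < 1), 2L)
})

test_that("concept substitution hits categorization but not detection", {
  onto <- generate_ontology(4, 2, seed = 13)
  doc <- generate_bb_document(bb_profile(multi_concept_rate = 0), onto,
                              seed = 14)
  p <- perturb_entities(doc, error_spec(n_substitute = 2, seed = 15), onto)
  sc <- score_subtask1(doc, p$prediction, onto)
  expect_equal(sc$detection$SER, 0)
  expect_gt(sc$categorization$substitution, 0)
  expect_gt(sc$official$substitution, 0)
})

test_that("event self-comparison is perfect in sub-task 2", {
  onto <- generate_ontology(3, 2, seed = 2)
  doc <- generate_bb_document(bb_profile(events_per_doc = 8), onto,
                              seed = 41)
  es <- score_events(doc, doc, subtask = 2)
  expect_equal(es$overall$recall, 1)
  expect_equal(es$overall$precision, 1)
  expect_equal(es$overall$f1, 1)
})

test_that("any member of a bacteria equivalence set validates the event", {
  text <- "Bacillus grows in soil. Bacillus persists."
  base_entities <- list(entity("T1", "Bacteria", "0 8"),
                        entity("T2", "Habitat", "18 22"),
                        entity("T3", "Bacteria", "24 32"))
  ref <- standoff_document("d", text, base_entities,
    events = list(event("E1", "Localization",
                        c(Bacterium = "T1", Localization = "T2"))),
    equivalences = list(c("T1", "T3")))
  # prediction uses the other, non-annotated member of the set
  pred_eq <- standoff_document("d", text, base_entities,
    events = list(event("E1", "Localization",
                        c(Bacterium = "T3", Localization = "T2"))))
  es <- score_events(ref, pred_eq, subtask = 2)
  expect_equal(es$overall$recall, 1)
  expect_equal(es$overall$precision, 1)
  # without the equivalence set the same prediction fails
  ref_noeq <- standoff_document("d", text, base_entities,
    events = list(event("E1", "Localization",
                        c(Bacterium = "T1", Localization = "T2"))))
  es2 <- score_events(ref_noeq, pred_eq, subtask = 2)
  expect_equal(es2$overall$recall, 0)
})

test_that("a graded habitat argument contributes its Se to the score", {
  text <- "Bacillus grows in thermal spring waters."
  ref <- standoff_document("d", text,
    list(entity("T1", "Bacteria", "0 8"),
         entity("T2", "Habitat", "18 32")),   # "thermal spring"
    events = list(event("E1", "Localization",
                        c(Bacterium = "T1", Localization = "T2"))))
  pred <- standoff_document("d", text,
    list(entity("T1", "Bacteria", "0 8"),
         entity("T2", "Habitat", "25 39")),   # overlaps 7 of 21
    events = list(event("E1", "Localization",
                        c(Bacterium = "T1", Localization = "T2"))))
  es <- score_events(ref, pred, subtask = 3)
  expect_equal(es$overall$recall, 1 / 3)
  # relaxed boundaries lift any overlap to full credit
  relaxed <- score_events(ref, pred, subtask = 3, relax_boundaries = TRUE)
  expect_equal(relaxed$overall$recall, 1)
})

test_that("PartOf grades both habitat arguments multiplicatively", {
  text <- "animal gut and animal liver tissue."
  mk <- function(host_frag, part_frag) {
    standoff_document("d", text,
      list(entity("T1", "Habitat", host_frag),
           entity("T2", "Habitat", part_frag)),
      events = list(event("E1", "PartOf", c(Host = "T1", Part = "T2"))))
  }
  ref <- mk("0 10", "15 27")
  pred <- mk("0 10", "15 27")
  expect_equal(score_events(ref, pred, subtask = 2)$overall$recall, 1)
  half <- mk("0 5", "15 21") # Se = 5/10 and 6/12
  es <- score_events(ref, half, subtask = 2)
  expect_equal(es$overall$recall, 0.5 * 0.5)
})

test_that("relaxed-boundary event scores dominate official scores", {
  onto <- generate_ontology(3, 2, seed = 6)
  for (seed in 1:10) {
    doc <- generate_bb_document(bb_profile(events_per_doc = 6), onto,
                                seed = seed)
    pred <- jittered_event_prediction(doc)
    official <- score_events(doc, pred, subtask = 3)
    relaxed <- score_events(doc, pred, subtask = 3,
                            relax_boundaries = TRUE)
    expect_gte(relaxed$overall$f1, official$overall$f1)
  }
})

test_that("intra-sentence mode filters cross-sentence events", {
  onto <- generate_ontology(3, 2, seed = 2)
  doc <- generate_bb_document(bb_profile(events_per_doc = 10,
                                         intra_sentence_rate = 0.3),
                              onto, seed = 77)
  full <- score_events(doc, doc, subtask = 2)
  intra <- score_events(doc, doc, subtask = 2, intra_sentence = TRUE)
  expect_lte(intra$overall$N, full$overall$N)
  expect_equal(intra$overall$recall, 1)
  nospans <- doc
  nospans$sentence_spans <- NULL
  expect_error(score_events(nospans, nospans, subtask = 2,
                            intra_sentence = TRUE),
               class = "bteval_config_error")
  fallback <- score_events(nospans, nospans, subtask = 2,
                           intra_sentence = TRUE, sentence_fallback = TRUE)
  expect_true(fallback$heuristic_sentences)
})

test_that("entities outside any event never affect event scores", {
  text <- "Bacillus grows in soil. Unused habitat words."
  mk <- function(extra) {
    ents <- list(entity("T1", "Bacteria", "0 8"),
                 entity("T2", "Habitat", "18 22"))
    if (extra) ents <- c(ents, list(entity("T9", "Habitat", "31 38")))
    standoff_document("d", text, ents,
      events = list(event("E1", "Localization",
                          c(Bacterium = "T1", Localization = "T2"))))
  }
  with_extra <- score_events(mk(TRUE), mk(TRUE), subtask = 2)
  without <- score_events(mk(FALSE), mk(FALSE), subtask = 2)
  expect_equal(with_extra$overall, without$overall)
})

test_that("corpus aggregation pools counts (micro) or averages (macro)", {
  onto <- generate_ontology(3, 2, seed = 9)
  docs <- lapply(1:3, function(s)
    generate_bb_document(bb_profile(), onto, seed = s))
  preds <- lapply(docs, function(d)
    perturb_entities(d, error_spec(n_delete = 1, seed = 5), onto)$prediction)
  scores <- Map(function(r, p) score_subtask1(r, p, onto), docs, preds)
  micro <- aggregate_entity_scores(scores)
  Ns <- vapply(scores, function(s) s$official$N, 0)
  expect_equal(micro$official$N, sum(Ns))
  expect_equal(micro$official$SER, (3 + sum(vapply(scores, function(s)
    s$official$substitution, 0))) / sum(Ns))
  macro <- aggregate_entity_scores(scores, macro = TRUE)
  expect_equal(macro$official$SER,
               mean(vapply(scores, function(s) s$official$SER, 0)))
})
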