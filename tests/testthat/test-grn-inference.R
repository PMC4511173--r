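# Two-sentence document exercising both inference chains: a nested-event
# interaction (gerE represses cwlH transcription) and a molecular binding
# chain (sigK on the cotD promoter).
worked_example_document <- function() {
  text <- paste0("gerE inhibits transcription of cwlH. ",
                 "sigK binds the promoter of cotD.")
  standoff_document("worked-example", text,
    entities = list(
      entity("T1", "Protein", "0 4"),    # gerE
      entity("T2", "Gene", "31 35"),     # cwlH
      entity("T3", "Protein", "37 41"),  # sigK
      entity("T4", "Promoter", "52 60"),
      entity("T5", "Gene", "64 68"),     # cotD
      entity("T6", "Site", "52 60")
    ),
    events = list(
      event("E1", "Transcription", c(Gene = "T2")),
      event("E2", "Interaction:Regulation", c(Agent = "T1", Target = "E1")),
      event("E3", "Bind_to", c(Agent = "T3", Site = "T6")),
      event("E4", "Site_of", c(Site = "T6", Target = "T4")),
      event("E5", "Promoter_of", c(Promoter = "T4", Gene = "T5"))
    ))
}

test_that("arguments reduce to their participating genes", {
  doc <- worked_example_document()
  expect_equal(reduce_to_genes(doc, "E1"), "cwlH")  # event -> participant
  expect_equal(reduce_to_genes(doc, "T2"), "cwlH")  # identity reduction
  expect_equal(reduce_to_genes(doc, "T4"), "cotD")  # promoter -> its gene
  expect_error(reduce_to_genes(doc, "T99"),
               class = "bteval_reduction_error")
})

test_that("nested events reduce to the union of their genes", {
  doc <- standoff_document("nest", "x y",
    entities = list(entity("T1", "Gene", "0 1"),
                    entity("T2", "Gene", "2 3")),
    events = list(
      event("E1", "Transcription", c(Gene = "T1")),
      event("E2", "Interaction:Binding", c(Agent = "T2", Target = "E1")),
      event("E3", "Interaction:Regulation", c(Agent = "T1", Target = "E2"))))
  expect_setequal(reduce_to_genes(doc, "E2"), c("x", "y"))
  expect_setequal(reduce_to_genes(doc, "E3"), c("x", "y"))
})

test_that("normalizations override surfaces as gene names", {
  doc <- standoff_document("norm", "GerE protein",
    entities = list(entity("T1", "Protein", "0 4")),
    normalizations = list(normalization("N1", "T1", "gerE",
                                        type = "Gene")))
  expect_equal(reduce_to_genes(doc, "T1"), "gerE")
})

test_that("molecular rules derive the binding chain and are idempotent", {
  doc <- worked_example_document()
  once <- apply_molecular_rules(doc)
  derived <- setdiff(names(once$events), names(doc$events))
  types <- sort(unname(vapply(once$events[derived], `[[`, "", "type")))
  expect_equal(types, c("Interaction:Binding", "Master_of_Promoter"))
  mop <- Filter(function(e) e$type == "Master_of_Promoter",
                once$events)[[1]]
  expect_equal(mop$args, c(Agent = "T3", Promoter = "T4"))
  twice <- apply_molecular_rules(once)
  expect_identical(names(twice$events), names(once$events))

  # no molecular premises -> unchanged
  flat <- standoff_document("flat", "a b",
    entities = list(entity("T1", "Gene", "0 1"),
                    entity("T2", "Gene", "2 3")),
    events = list(event("E1", "Interaction:Activation",
                        c(Agent = "T1", Target = "T2"))))
  expect_identical(apply_molecular_rules(flat)$events, flat$events)
})

test_that("regulon membership derives generic Regulation interactions", {
  doc <- standoff_document("reg", "sigF ctc spoIIGA regulon",
    entities = list(entity("T1", "Protein", "0 4"),
                    entity("T2", "Gene", "5 8"),
                    entity("T3", "Gene", "9 16"),
                    entity("T4", "Regulon", "17 24")),
    events = list(
      event("E1", "Master_of_Regulon", c(Agent = "T1", Regulon = "T4")),
      event("E2", "Member_of_Regulon", c(Gene = "T2", Regulon = "T4")),
      event("E3", "Member_of_Regulon", c(Gene = "T3", Regulon = "T4"))))
  net <- infer_network(doc)
  expect_equal(nrow(net$arcs), 2L)
  expect_true(all(net$arcs$agent == "sigF"))
  expect_true(all(net$arcs$label == "Regulation"))
  expect_setequal(net$arcs$target, c("ctc", "spoIIGA"))
})

test_that("the two-example document infers a network with exactly 2 arcs", {
  net <- infer_network(worked_example_document())
  expect_equal(nrow(net$arcs), 2L)
  expect_true(any(net$arcs$agent == "gerE" & net$arcs$target == "cwlH" &
                    net$arcs$label == "Regulation"))
  expect_true(any(net$arcs$agent == "sigK" & net$arcs$target == "cotD" &
                    net$arcs$label == "Binding"))
})

test_that("repeated interactions collapse to a single arc", {
  doc <- worked_example_document()
  net1 <- infer_network(doc)
  net3 <- infer_network(list(doc, doc, doc))
  expect_identical(net3$arcs, net1$arcs)
})

test_that("inference is a fixpoint and monotone in the annotations", {
  doc <- worked_example_document()
  once <- apply_molecular_rules(doc)
  expect_identical(infer_network(apply_molecular_rules(once))$arcs,
                   infer_network(once)$arcs)
  # adding an annotation never removes arcs
  bigger <- doc
  bigger$events[["E9"]] <- event("E9", "Interaction:Activation",
                                 c(Agent = "T3", Target = "T2"))
  arcs_small <- infer_network(doc)$arcs
  arcs_big <- infer_network(bigger)$arcs
  small_keys <- paste(arcs_small$agent, arcs_small$label, arcs_small$target)
  big_keys <- paste(arcs_big$agent, arcs_big$label, arcs_big$target)
  expect_true(all(small_keys %in% big_keys))
})

test_that("direct arc-list submissions equal inference over flat events", {
  net <- generate_network(6, 8, seed = 31)
  doc <- network_to_document(net)
  expect_length(validate_document(doc, "grn"), 0L)
  expect_identical(infer_network(doc)$arcs, net$arcs)
})

test_that("provisional rules stay out of the default registry", {
  expect_false(any(vapply(grn_rules(), `[[`, TRUE, "provisional")))
  all_rules <- grn_rules(include_provisional = TRUE)
  expect_gt(length(all_rules), length(grn_rules()))
})

test_that("excessive nesting depth raises an error", {
  ents <- list(entity("T1", "Gene", "0 1"))
  evs <- list(event("E1", "Transcription", c(Gene = "T1")))
  for (i in 2:13) {
    evs[[i]] <- event(paste0("E", i), "Interaction:Regulation",
                      c(Agent = "T1", Target = paste0("E", i - 1L)))
  }
  doc <- standoff_document("deep", "x y", entities = ents, events = evs)
  expect_error(reduce_to_genes(doc, "E13"),
               class = "bteval_reduction_error")
})
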